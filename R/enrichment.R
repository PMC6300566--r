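# Over-representation testing and resampling calibration.
#
# The uncorrected statistic is the one-sided hypergeometric upper tail
# (Fisher's exact test, over-representation side). Calibration follows the
# resampling recipe: for each test set, an ensemble of size-matched random
# null sets is drawn from the universe; for each pathway the fraction of
# null-set uncorrected p-values <= the observed uncorrected p-value is the
# empirical p-value. With n_null nulls the empirical p has granularity
# 1/n_null and may be exactly 0, which the disease scoring stage floors.

#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability `P(X >= overlap)` for
#' `X ~ Hypergeometric(universe_size, pathway_size, set_size)`: the chance
#' that a uniform random set of `set_size` genes hits the pathway at least
#' `overlap` times. Returns 1 when `overlap` is 0. Vectorized over
#' `overlap` (and the other arguments, recycled).
#'
#' @param set_size size of the test gene set.
#' @param pathway_size size of the pathway within the universe.
#' @param overlap observed intersection size.
#' @param universe_size size of the gene universe.
#' @return Numeric p-value(s) in (0, 1\].
#' @export
overlap_pvalue <- function(set_size, pathway_size, overlap, universe_size) {
  n <- max(length(set_size), length(pathway_size), length(overlap),
           length(universe_size))
  set_size <- rep_len(set_size, n)
  pathway_size <- rep_len(pathway_size, n)
  overlap <- rep_len(overlap, n)
  universe_size <- rep_len(universe_size, n)
  if (any(overlap < 0) || any(overlap > pmin(pathway_size, set_size))) {
    stopf("overlap must lie in [0, min(pathway_size, set_size)]")
  }
  if (any(pathway_size > universe_size) || any(set_size > universe_size)) {
    stopf("pathway_size and set_size must not exceed universe_size")
  }
  # phyper accumulates in log space internally and is stable for
  # universes well beyond 1e6
  p <- stats::phyper(overlap - 1, pathway_size, universe_size - pathway_size,
                     set_size, lower.tail = FALSE)
  p[overlap == 0] <- 1
  p
}

#' Sample size-matched null gene sets
#'
#' Draws `n_sets` independent gene sets of size `set_size`, each uniform
#' without replacement from the universe — the "random selection from the
#' genome" null ensemble used for calibration.
#'
#' @param universe character vector of gene symbols.
#' @param set_size size of each null set; must not exceed the universe.
#' @param n_sets number of null sets (1,000 in the reference analysis).
#' @param seed integer seed.
#' @return List of `n_sets` character vectors.
#' @export
sample_null_sets <- function(universe, set_size, n_sets = 1000L, seed = 1L) {
  set_size <- assert_count(set_size, "set_size", 1L)
  n_sets <- assert_count(n_sets, "n_sets", 1L)
  if (set_size > length(universe)) {
    stopf("set_size %d exceeds universe size %d", set_size, length(universe))
  }
  withr::with_seed(seed,
    lapply(seq_len(n_sets), function(i) sample(universe, set_size)))
}

#' Empirical p-value against a null distribution
#'
#' The fraction of null uncorrected p-values smaller than or equal to the
#' observed uncorrected p-value. May be exactly 0 (no null set is as
#' enriched); every nonzero value is at least `1/length(null_p)`.
#'
#' @param observed_p observed uncorrected p-value.
#' @param null_p non-empty numeric vector of null uncorrected p-values.
#' @param pseudo_count if TRUE, use the (count + 1) / (n + 1) variant that
#'   cannot return 0. OFF by default: the downstream zero floor implements
#'   the reference zero handling.
#' @return Empirical p-value in \[0, 1\].
#' @export
empirical_pvalue <- function(observed_p, null_p, pseudo_count = FALSE) {
  if (!length(null_p)) stopf("null_p must be non-empty")
  assert_prob(null_p, "null_p")
  assert_prob(observed_p, "observed_p")
  k <- sum(null_p <= observed_p)
  if (pseudo_count) (k + 1) / (length(null_p) + 1) else k / length(null_p)
}

#' Compute the full empirical enrichment matrix
#'
#' For each interactome a null ensemble matched to its size is drawn (with
#' a sub-seed derived from `master_seed` and the interactome name); for
#' each pathway, the interactome's uncorrected hypergeometric p-value is
#' calibrated against that pathway's null distribution of uncorrected
#' p-values.
#'
#' Interactome members and pathway genes outside the universe are dropped
#' with a message; an interactome left empty is an error.
#'
#' @param interactomes list of `interactome` objects (see
#'   [extract_interactome()]).
#' @param pathways a [pathway_collection()].
#' @param universe character vector of gene symbols (background).
#' @param n_null number of null sets per interactome.
#' @param master_seed integer master seed.
#' @param pseudo_count passed to [empirical_pvalue()].
#' @return An object of class `enrichment_matrix` with matrices
#'   `empirical_p`, `uncorrected_p`, `overlap` (rows = interactomes,
#'   columns = pathway ids), the per-interactome null p-value arrays
#'   (`null_p`, a list of n_null x n_pathway matrices), `n_null` and
#'   `seed`.
#' @export
enrich_matrix <- function(interactomes, pathways, universe, n_null = 1000L,
                          master_seed = 1L, pseudo_count = FALSE) {
  n_null <- assert_count(n_null, "n_null", 1L)
  universe <- unique(as.character(universe))
  N <- length(universe)
  ids <- pathway_ids(pathways)
  if (!length(interactomes) || !length(ids)) {
    stopf("need at least one interactome and one pathway")
  }
  names(interactomes) <- vapply(interactomes, `[[`, "", "name")

  pw_idx <- lapply(pathways$genes, function(g) {
    idx <- match(g, universe)
    idx[!is.na(idx)]
  })
  dropped_pw <- sum(lengths(pathways$genes) - lengths(pw_idx))
  if (dropped_pw > 0) {
    message(sprintf("enrich_matrix: dropped %d pathway gene(s) outside the universe",
                    dropped_pw))
  }
  K <- lengths(pw_idx)
  pw_memb <- lapply(pw_idx, function(idx) {
    v <- logical(N); v[idx] <- TRUE; v
  })

  nm <- names(interactomes)
  emp <- unc <- ov <- matrix(NA_real_, length(nm), length(ids),
                             dimnames = list(nm, ids))
  null_p_all <- stats::setNames(vector("list", length(nm)), nm)

  for (i in seq_along(interactomes)) {
    members <- interactomes[[i]]$members
    idx <- match(members, universe)
    n_drop <- sum(is.na(idx))
    if (n_drop > 0) {
      message(sprintf("enrich_matrix: dropped %d member(s) of '%s' outside the universe",
                      n_drop, nm[i]))
      idx <- idx[!is.na(idx)]
    }
    if (!length(idx)) {
      stopf("interactome '%s' is empty after universe restriction", nm[i])
    }
    set_size <- length(idx)

    nulls <- sample_null_sets(universe, set_size, n_null,
                              derive_seed(master_seed, 17L, nm[i]))
    null_mat <- matrix(match(unlist(nulls), universe), nrow = set_size)

    null_p <- matrix(NA_real_, n_null, length(ids),
                     dimnames = list(NULL, ids))
    for (j in seq_along(ids)) {
      memb <- pw_memb[[j]]
      obs_ov <- sum(memb[idx])
      null_ov <- colSums(matrix(memb[null_mat], nrow = set_size))
      np <- overlap_pvalue(set_size, K[j], null_ov, N)
      op <- overlap_pvalue(set_size, K[j], obs_ov, N)
      ov[i, j] <- obs_ov
      unc[i, j] <- op
      null_p[, j] <- np
      emp[i, j] <- empirical_pvalue(op, np, pseudo_count = pseudo_count)
    }
    null_p_all[[i]] <- null_p
  }

  structure(list(empirical_p = emp, uncorrected_p = unc, overlap = ov,
                 null_p = null_p_all, n_null = n_null,
                 seed = as.integer(master_seed)),
            class = "enrichment_matrix")
}

#' @export
print.enrichment_matrix <- function(x, ...) {
  cat(sprintf("enrichment_matrix: %d interactomes x %d pathways (n_null = %d, seed = %d)\n",
              nrow(x$empirical_p), ncol(x$empirical_p), x$n_null, x$seed))
  invisible(x)
}

#' Long-format view of an enrichment matrix
#'
#' @param matrix an [enrich_matrix()] result.
#' @return Data frame with columns `interactome`, `pathway`, `overlap`,
#'   `uncorrected_p`, `empirical_p`.
#' @export
enrichment_long <- function(matrix) {
  stopifnot(inherits(matrix, "enrichment_matrix"))
  rows <- rownames(matrix$empirical_p)
  cols <- colnames(matrix$empirical_p)
  data.frame(
    interactome = rep(rows, times = length(cols)),
    pathway = rep(cols, each = length(rows)),
    overlap = as.vector(matrix$overlap),
    uncorrected_p = as.vector(matrix$uncorrected_p),
    empirical_p = as.vector(matrix$empirical_p),
    stringsAsFactors = FALSE)
}
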
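# Disease-level scoring: geometric-mean combination of the per-disease
# block of empirical p-values, the sensitivity index 1/p_mean, ranking,
# and per-category score summaries.

#' Default zero floor for empirical p-values
#'
#' With 1,000 null sets the smallest nonzero empirical p-value is 1e-3 and
#' zeros are replaced by 1e-4 — one decade below the resampling resolution.
#' For other null counts the same intent is preserved: `1 / (10 * n_null)`.
#'
#' @param n_null number of null sets used for calibration.
#' @return The zero floor.
#' @export
default_zero_floor <- function(n_null = 1000L) {
  1 / (10 * as.numeric(n_null))
}

#' Geometric-mean combination of p-values
#'
#' `p_mean = (p1 * p2 * ... * pn)^(1/n)`, computed in log space after
#' replacing every value below `zero_floor` by `zero_floor` (in particular
#' the exact zeros the resampling can produce).
#'
#' @param p_values non-empty numeric vector of p-values in \[0, 1\].
#' @param zero_floor replacement floor, default 1e-4.
#' @return The floored geometric mean, in `[zero_floor, 1]`.
#' @export
combine_pvalues <- function(p_values, zero_floor = 1e-4) {
  if (!length(p_values)) stopf("p_values must be non-empty")
  assert_prob(p_values, "p_values")
  if (zero_floor <= 0 || zero_floor > 1) stopf("zero_floor must lie in (0, 1]")
  p <- pmax(p_values, zero_floor)
  exp(mean(log(p)))
}

#' Lithium sensitivity index
#'
#' The reciprocal of the combined mean p-value; larger values indicate a
#' stronger predicted sensitivity of the disease to lithium.
#'
#' @param p_mean combined p-value in (0, 1\].
#' @return `1 / p_mean`.
#' @export
sensitivity_index <- function(p_mean) {
  if (any(p_mean <= 0) || any(p_mean > 1)) stopf("p_mean must lie in (0, 1]")
  1 / p_mean
}

#' Score a single disease
#'
#' Gathers the empirical p-values of every (interactome, disease pathway)
#' cell — strong and weak enrichments alike — and combines them.
#'
#' @param matrix an [enrich_matrix()] result.
#' @param disease disease name.
#' @param catalog a [disease_catalog()].
#' @param zero_floor zero replacement floor; defaults to
#'   [default_zero_floor()] of the matrix's `n_null`.
#' @return An object of class `combined_score`: list with `disease`,
#'   `category`, `p_values`, `n`, `p_mean`, `sensitivity_index`,
#'   `zero_floor`.
#' @export
score_disease <- function(matrix, disease, catalog,
                          zero_floor = default_zero_floor(matrix$n_null)) {
  stopifnot(inherits(matrix, "enrichment_matrix"))
  if (!(disease %in% names(catalog$diseases))) {
    stopf("unknown disease '%s'", disease)
  }
  pw <- catalog$diseases[[disease]]
  missing <- setdiff(pw, colnames(matrix$empirical_p))
  if (length(missing)) {
    stopf("disease '%s': pathway(s) missing from matrix: %s",
          disease, paste(missing, collapse = ", "))
  }
  p <- as.vector(matrix$empirical_p[, pw, drop = FALSE])
  pm <- combine_pvalues(p, zero_floor)
  structure(list(disease = disease,
                 category = unname(catalog$category[[disease]]),
                 p_values = p, n = length(p), p_mean = pm,
                 sensitivity_index = sensitivity_index(pm),
                 zero_floor = zero_floor),
            class = "combined_score")
}

#' Score every disease in a catalog
#'
#' @inheritParams score_disease
#' @return List of `combined_score` objects, one per catalog disease.
#' @export
score_all_diseases <- function(matrix, catalog,
                               zero_floor = default_zero_floor(matrix$n_null)) {
  lapply(names(catalog$diseases), function(d) {
    score_disease(matrix, d, catalog, zero_floor)
  })
}

#' Rank diseases by sensitivity index
#'
#' Descending by sensitivity index; ties broken by disease name for
#' determinism. The printed table shows `p_mean` at 4 decimals and the
#' index at full precision, mirroring the reference report layout; the
#' underlying data frame keeps full precision throughout.
#'
#' @param scores list of `combined_score` objects.
#' @param catalog a [disease_catalog()] (category lookup).
#' @return A data frame of class `disease_ranking` with columns `rank`,
#'   `disease`, `category`, `p_mean`, `sensitivity_index`.
#' @export
rank_diseases <- function(scores, catalog) {
  if (!length(scores)) stopf("scores must be non-empty")
  disease <- vapply(scores, `[[`, "", "disease")
  if (anyDuplicated(disease)) {
    stopf("duplicate disease name '%s'", disease[duplicated(disease)][1])
  }
  idx <- vapply(scores, `[[`, 0, "sensitivity_index")
  pm <- vapply(scores, `[[`, 0, "p_mean")
  o <- order(-idx, disease)
  out <- data.frame(rank = seq_along(o), disease = disease[o],
                    category = unname(catalog$category[disease[o]]),
                    p_mean = pm[o], sensitivity_index = idx[o],
                    stringsAsFactors = FALSE)
  class(out) <- c("disease_ranking", "data.frame")
  out
}

#' @export
print.disease_ranking <- function(x, ...) {
  shown <- data.frame(rank = x$rank, disease = x$disease,
                      category = x$category,
                      sensitivity_index = x$sensitivity_index,
                      p_mean = sprintf("%.4f", x$p_mean),
                      stringsAsFactors = FALSE)
  print.data.frame(shown, row.names = FALSE)
  invisible(x)
}

#' Per-category summary of log10 sensitivity indices
#'
#' For each disease category reports n, min, quartiles, median and max of
#' `log10(sensitivity_index)` — the plot-ready analogue of the box-plot
#' comparison between null sets, metabolic pathways and nervous-system
#' disease pathways.
#'
#' @param scores list of `combined_score` objects.
#' @param catalog a [disease_catalog()].
#' @return Data frame with columns `category`, `n`, `min`, `q1`, `median`,
#'   `q3`, `max`.
#' @export
category_summary <- function(scores, catalog) {
  disease <- vapply(scores, `[[`, "", "disease")
  lidx <- log10(vapply(scores, `[[`, 0, "sensitivity_index"))
  cats <- unname(catalog$category[disease])
  rows <- lapply(sort(unique(cats)), function(cc) {
    v <- lidx[cats == cc]
    q <- stats::quantile(v, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    data.frame(category = cc, n = length(v), min = q[1], q1 = q[2],
               median = q[3], q3 = q[4], max = q[5],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
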
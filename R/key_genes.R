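# Key-gene scoring: how often a gene sits at the cross section of an
# interactome and a disease pathway, normalized per disease by pathway
# count and summed across diseases.

#' Cross-section gene counts for one disease
#'
#' `count(g)` is the number of (interactome, disease pathway) pairs whose
#' intersection contains `g`. Genes with count 0 are omitted. Optionally
#' restricted to pairs whose empirical p-value passes a significance cut.
#'
#' @param interactomes list of `interactome` objects.
#' @param disease disease name.
#' @param catalog a [disease_catalog()].
#' @param pathways a [pathway_collection()].
#' @param matrix optional [enrich_matrix()] result; required when
#'   `min_significance` is given.
#' @param min_significance optional empirical-p cutoff: only
#'   (interactome, pathway) pairs with `empirical_p <= min_significance`
#'   contribute. Default NULL counts all pairs.
#' @return Named integer vector gene -> count.
#' @export
cross_section_counts <- function(interactomes, disease, catalog, pathways,
                                 matrix = NULL, min_significance = NULL) {
  if (!(disease %in% names(catalog$diseases))) {
    stopf("unknown disease '%s'", disease)
  }
  if (!is.null(min_significance) && is.null(matrix)) {
    stopf("min_significance requires the enrichment matrix")
  }
  pw <- catalog$diseases[[disease]]
  hits <- character(0)
  for (ia in interactomes) {
    for (p in pw) {
      if (!is.null(min_significance) &&
          matrix$empirical_p[ia$name, p] > min_significance) next
      hits <- c(hits, intersect(ia$members, pathways$genes[[p]]))
    }
  }
  if (!length(hits)) return(stats::setNames(integer(0), character(0)))
  tab <- table(hits)
  stats::setNames(as.integer(tab), names(tab))
}

#' Normalize cross-section counts by pathway count
#'
#' @param counts named integer vector from [cross_section_counts()].
#' @param n_pathways number of pathways associated with the disease.
#' @return Named numeric vector of mean counts (full precision; exports
#'   print 2 decimals).
#' @export
normalize_counts <- function(counts, n_pathways) {
  n_pathways <- assert_count(n_pathways, "n_pathways", 1L)
  counts / n_pathways
}

#' Assemble the key-gene score table
#'
#' One row per gene appearing in any disease's cross section, one column
#' per disease (missing values 0) plus a `Sum` column; rows sorted by
#' descending sum, ties by gene name. Sums are computed from unrounded
#' values; exports round to 2 decimals only at print time.
#'
#' @param normalized named list disease -> named numeric vector (output of
#'   [normalize_counts()] per disease).
#' @param disease_order column order; defaults to `names(normalized)`.
#' @return Data frame with columns `gene`, one per disease, and `Sum`.
#' @export
gene_score_table <- function(normalized, disease_order = names(normalized)) {
  if (!length(normalized)) stopf("need at least one disease")
  stopifnot(all(disease_order %in% names(normalized)))
  genes <- sort(unique(unlist(lapply(normalized, names))))
  if (!length(genes)) {
    out <- as.data.frame(stats::setNames(
      c(list(character(0)), rep(list(numeric(0)), length(disease_order) + 1L)),
      c("gene", disease_order, "Sum")), check.names = FALSE)
    return(out)
  }
  m <- sapply(disease_order, function(d) {
    v <- normalized[[d]][genes]
    v[is.na(v)] <- 0
    unname(v)
  })
  m <- matrix(m, nrow = length(genes),
              dimnames = list(NULL, disease_order))
  sums <- rowSums(m)
  o <- order(-sums, genes)
  out <- data.frame(gene = genes[o], m[o, , drop = FALSE], Sum = sums[o],
                    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Key-gene scores for a whole study
#'
#' Convenience wrapper running [cross_section_counts()] and
#' [normalize_counts()] for every catalog disease and assembling the
#' score table.
#'
#' @inheritParams cross_section_counts
#' @return Data frame as in [gene_score_table()].
#' @export
key_gene_scores <- function(interactomes, catalog, pathways, matrix = NULL,
                            min_significance = NULL) {
  normalized <- lapply(names(catalog$diseases), function(d) {
    cnt <- cross_section_counts(interactomes, d, catalog, pathways,
                                matrix, min_significance)
    normalize_counts(cnt, length(catalog$diseases[[d]]))
  })
  names(normalized) <- names(catalog$diseases)
  gene_score_table(normalized)
}
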
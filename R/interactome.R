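# Interactome extraction: confidence-thresholded k-hop neighborhoods of a
# seed gene, size-window tuning of (threshold, order), and merging of
# near-duplicate interactomes by Jaccard similarity.

#' Interactome extraction parameters
#'
#' @param seed_gene seed gene symbol.
#' @param confidence_threshold minimum edge confidence in \[0, 1\]; applies
#'   to every edge on a path (both hops of an order-2 path).
#' @param order neighborhood order, 1 (direct interactions) or 2 (one
#'   intermediary allowed).
#' @return An object of class `interactome_spec`.
#' @export
interactome_spec <- function(seed_gene, confidence_threshold, order) {
  if (!is.character(seed_gene) || length(seed_gene) != 1L || !nzchar(seed_gene)) {
    stopf("seed_gene must be a single gene symbol")
  }
  assert_prob(confidence_threshold, "confidence_threshold")
  if (!(order %in% c(1L, 2L))) stopf("order must be 1 or 2")
  structure(list(seed_gene = seed_gene,
                 confidence_threshold = as.numeric(confidence_threshold),
                 order = as.integer(order)),
            class = "interactome_spec")
}

new_interactome <- function(name, members, spec, provenance = list()) {
  structure(list(name = name, members = sort(unique(members)),
                 spec = spec, provenance = provenance),
            class = "interactome")
}

#' @export
print.interactome <- function(x, ...) {
  cat(sprintf("interactome '%s': %d genes\n", x$name, length(x$members)))
  invisible(x)
}

#' Extract a seed-gene interactome
#'
#' Members are all genes reachable from the seed within `spec$order` hops
#' using only edges with confidence at or above the threshold; the seed is
#' always included.
#'
#' @param network an [interaction_network()].
#' @param spec an [interactome_spec()].
#' @return An `interactome` object named after the seed gene.
#' @export
extract_interactome <- function(network, spec) {
  stopifnot(inherits(spec, "interactome_spec"))
  seed <- spec$seed_gene
  if (!(seed %in% network$nodes)) {
    stopf("seed gene '%s' is not in the network", seed)
  }
  keep <- network$edges$confidence >= spec$confidence_threshold
  edges <- network$edges[keep, , drop = FALSE]
  members <- seed
  frontier <- seed
  for (hop in seq_len(spec$order)) {
    hit <- edges$gene_a %in% frontier | edges$gene_b %in% frontier
    nbr <- unique(c(edges$gene_a[hit], edges$gene_b[hit]))
    frontier <- setdiff(nbr, members)
    if (!length(frontier)) break
    members <- c(members, frontier)
  }
  new_interactome(seed, members, spec)
}

#' Tune interactome extraction to a target size window
#'
#' Evaluates every (threshold, order) candidate and returns the spec whose
#' interactome size lies in `size_window`, preferring (in order) lower
#' order, then higher threshold, then size closest to the window midpoint.
#' If no candidate lands in the window, the candidate with size closest to
#' the midpoint is returned and flagged.
#'
#' @param network an [interaction_network()].
#' @param seed_gene seed gene symbol.
#' @param size_window inclusive target size interval, default `c(100, 600)`
#'   ("a few hundred genes").
#' @param thresholds candidate confidence thresholds.
#' @param orders candidate neighborhood orders.
#' @return A list with elements `spec`, `interactome` and `in_window`
#'   (FALSE marks a flagged out-of-window result).
#' @export
tune_interactome <- function(network, seed_gene, size_window = c(100, 600),
                             thresholds = seq(0.4, 0.9, by = 0.1),
                             orders = c(1L, 2L)) {
  if (!length(thresholds) || !length(orders)) {
    stopf("candidate lists must be non-empty")
  }
  grid <- expand.grid(threshold = thresholds, order = orders,
                      KEEP.OUT.ATTRS = FALSE)
  cand <- lapply(seq_len(nrow(grid)), function(i) {
    sp <- interactome_spec(seed_gene, grid$threshold[i], grid$order[i])
    list(spec = sp, interactome = extract_interactome(network, sp))
  })
  sizes <- vapply(cand, function(x) length(x$interactome$members), 0L)
  mid <- mean(size_window)
  in_win <- sizes >= size_window[1] & sizes <= size_window[2]
  pool <- if (any(in_win)) which(in_win) else seq_along(cand)
  o <- order(grid$order[pool], -grid$threshold[pool],
             abs(sizes[pool] - mid))
  best <- pool[o[1]]
  list(spec = cand[[best]]$spec, interactome = cand[[best]]$interactome,
       in_window = in_win[best])
}

jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(1)
  length(intersect(a, b)) / u
}

#' Merge near-duplicate interactomes
#'
#' Single-linkage grouping of interactomes whose pairwise Jaccard index is
#' at or above the threshold; each group is replaced by the union of its
#' members, named by joining the sorted source names with "+". Provenance
#' (the source specs) is retained. Output is ordered by name.
#'
#' @param interactomes list of `interactome` objects.
#' @param jaccard_threshold Jaccard similarity threshold in (0, 1\];
#'   default 0.8 ("very similar").
#' @return List of `interactome` objects.
#' @export
merge_similar <- function(interactomes, jaccard_threshold = 0.8) {
  if (jaccard_threshold <= 0 || jaccard_threshold > 1) {
    stopf("jaccard_threshold must lie in (0, 1]")
  }
  n <- length(interactomes)
  if (n == 0L) return(list())
  # union-find over pairs at or above the threshold (single linkage)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      if (jaccard(interactomes[[i]]$members,
                  interactomes[[j]]$members) >= jaccard_threshold) {
        parent[find(j)] <- find(i)
      }
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  groups <- split(seq_len(n), roots)
  out <- lapply(groups, function(idx) {
    src <- interactomes[idx]
    if (length(idx) == 1L) return(src[[1]])
    nm <- paste(sort(vapply(src, `[[`, "", "name")), collapse = "+")
    new_interactome(nm, unlist(lapply(src, `[[`, "members")), "merged",
                    provenance = lapply(src, `[[`, "spec"))
  })
  out[order(vapply(out, `[[`, "", "name"))]
}
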
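# Shared fixtures and independent oracles used across the suite.

# Exhaustive hypergeometric upper-tail oracle: enumerate every n-subset of
# {1..N}, take the pathway to be {1..K} (WLOG by symmetry), and count the
# fraction of subsets with overlap >= k. Independent of phyper.
hyper_tail_enum <- function(N, K, n, k) {
  if (k == 0) return(1)
  sets <- utils::combn(N, n)
  mean(colSums(sets <= K) >= k)
}

# Brute-force cross-section oracle: double loop over (interactome, pathway)
# pairs, tallying per-gene membership of the intersection.
cross_section_brute <- function(interactomes, pathway_sets) {
  counts <- new.env()
  for (ia in interactomes) {
    for (pw in pathway_sets) {
      for (g in intersect(ia$members, pw)) {
        counts[[g]] <- (if (is.null(counts[[g]])) 0L else counts[[g]]) + 1L
      }
    }
  }
  out <- unlist(as.list(counts))
  if (is.null(out)) stats::setNames(integer(0), character(0))
  else out[order(names(out))]
}

# Three-node path fixture A -0.8- B -0.8- C used in the interactome tests.
path3_network <- function(c_ab = 0.8, c_bc = 0.8) {
  interaction_network(data.frame(gene_a = c("A", "B"),
                                 gene_b = c("B", "C"),
                                 confidence = c(c_ab, c_bc)))
}

# Random weighted graph on n nodes for property tests.
random_network <- function(n = 50, p = 0.12, seed = 1) {
  withr::with_seed(seed, {
    pairs <- t(utils::combn(n, 2))
    keep <- stats::runif(nrow(pairs)) < p
    interaction_network(
      data.frame(gene_a = sprintf("N%02d", pairs[keep, 1]),
                 gene_b = sprintf("N%02d", pairs[keep, 2]),
                 confidence = stats::runif(sum(keep))),
      nodes = sprintf("N%02d", seq_len(n)))
  })
}

# igraph-based neighborhood oracle (independent of the package BFS).
ego_oracle <- function(network, seed_gene, threshold, order) {
  keep <- network$edges$confidence >= threshold
  edf <- network$edges[keep, c("gene_a", "gene_b")]
  g <- igraph::graph_from_data_frame(
    edf, directed = FALSE,
    vertices = data.frame(name = network$nodes))
  sort(names(igraph::ego(g, order = order, nodes = seed_gene)[[1]]))
}

# Small synthetic configuration for fast end-to-end tests.
small_config <- function(master_seed = 11L, planted_fraction = 0.5) {
  synthetic_config(n_genes = 400, mean_degree = 8,
                   n_pathways = 16, pathway_size_range = c(10L, 25L),
                   n_diseases = 6, pathways_per_disease_range = c(1L, 2L),
                   n_seeds = 5, n_truth_diseases = 2, seeds_per_truth = 2,
                   planted_fraction = planted_fraction,
                   planted_confidence = 0.9,
                   master_seed = master_seed)
}

new_interactome_for_test <- function(name, members) {
  lisindex:::new_interactome(name, members,
                             interactome_spec(name, 0.4, 1L))
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
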
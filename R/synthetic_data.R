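# Synthetic study generator.
#
# Stands in for the STRING network + KEGG pathway inputs: an Erdos-Renyi
# gene network with Beta-distributed edge confidences, uniform random
# pathway gene sets, a disease catalog grouping 1-3 pathways per disease,
# and PLANTED excess overlap between chosen seed-gene neighborhoods and
# the pathways of chosen ("nervous") diseases, so calibration and ranking
# recovery are testable without any database download.

#' Synthetic study configuration
#'
#' Defaults describe the stated synthetic world: 2,000 genes at mean degree
#' 20 with Beta(2, 2) confidences, 60 pathways of 20-100 genes, 20 diseases
#' of 1-3 pathways, and 10 seed genes. Signal is planted for 2 "nervous"
#' diseases, each receiving direct seed-to-pathway edges from 3 distinct
#' seed genes at confidence 0.9 covering half of each pathway.
#'
#' @param n_genes number of genes in the universe.
#' @param mean_degree expected node degree of the random network.
#' @param confidence_beta_params shape parameters (a, b) of the Beta
#'   distribution edge confidences are drawn from.
#' @param n_pathways number of pathway gene sets.
#' @param pathway_size_range inclusive integer range of pathway sizes.
#' @param n_diseases number of diseases in the catalog.
#' @param pathways_per_disease_range inclusive integer range of pathways
#'   per disease.
#' @param n_seeds number of seed (lithium-sensitive analogue) genes.
#' @param n_truth_diseases number of diseases that receive planted signal
#'   (labelled "nervous"); remaining diseases alternate "metabolic"/"null".
#' @param seeds_per_truth number of distinct seed genes planted into each
#'   truth disease.
#' @param planted_fraction fraction of each truth pathway wired directly to
#'   the planted seed gene (0 disables planting).
#' @param planted_confidence confidence assigned to planted edges.
#' @param master_seed integer master seed; all component seeds derive from
#'   it deterministically.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 2000,
                             mean_degree = 20,
                             confidence_beta_params = c(2, 2),
                             n_pathways = 60,
                             pathway_size_range = c(20L, 100L),
                             n_diseases = 20,
                             pathways_per_disease_range = c(1L, 3L),
                             n_seeds = 10,
                             n_truth_diseases = 2,
                             seeds_per_truth = 3,
                             planted_fraction = 0.5,
                             planted_confidence = 0.9,
                             master_seed = 1L) {
  n_genes <- assert_count(n_genes, "n_genes", 1L)
  n_pathways <- assert_count(n_pathways, "n_pathways", 0L)
  n_diseases <- assert_count(n_diseases, "n_diseases", 0L)
  n_seeds <- assert_count(n_seeds, "n_seeds", 1L)
  n_truth_diseases <- assert_count(n_truth_diseases, "n_truth_diseases", 0L)
  seeds_per_truth <- assert_count(seeds_per_truth, "seeds_per_truth", 1L)
  if (mean_degree < 0 || mean_degree >= n_genes) {
    stopf("mean_degree must lie in [0, n_genes - 1)")
  }
  if (length(confidence_beta_params) != 2L || any(confidence_beta_params <= 0)) {
    stopf("confidence_beta_params must be two positive reals")
  }
  rng_ok <- function(r) length(r) == 2L && r[1] <= r[2] && r[1] >= 1
  if (!rng_ok(pathway_size_range) || pathway_size_range[2] > n_genes) {
    stopf("pathway_size_range must be a non-empty range within [1, n_genes]")
  }
  if (!rng_ok(pathways_per_disease_range) ||
      (n_diseases > 0 && n_pathways > 0 &&
       pathways_per_disease_range[2] > n_pathways)) {
    stopf("pathways_per_disease_range must be a non-empty range within [1, n_pathways]")
  }
  assert_prob(planted_fraction, "planted_fraction")
  assert_prob(planted_confidence, "planted_confidence")
  if (n_truth_diseases > n_diseases) stopf("n_truth_diseases exceeds n_diseases")
  if (seeds_per_truth > n_seeds) stopf("seeds_per_truth exceeds n_seeds")
  if (n_seeds > n_genes) stopf("n_seeds exceeds n_genes")
  structure(list(n_genes = n_genes, mean_degree = mean_degree,
                 confidence_beta_params = as.numeric(confidence_beta_params),
                 n_pathways = n_pathways,
                 pathway_size_range = as.integer(pathway_size_range),
                 n_diseases = n_diseases,
                 pathways_per_disease_range = as.integer(pathways_per_disease_range),
                 n_seeds = n_seeds,
                 n_truth_diseases = n_truth_diseases,
                 seeds_per_truth = seeds_per_truth,
                 planted_fraction = planted_fraction,
                 planted_confidence = planted_confidence,
                 master_seed = as.integer(master_seed)),
            class = "synthetic_config")
}

#' Generate the gene universe
#'
#' @param n_genes number of genes (>= 1).
#' @param seed integer seed (reserved for future symbol shuffling; current
#'   symbols are deterministic regardless).
#' @return Character vector `G000001`, `G000002`, ...
#' @export
generate_universe <- function(n_genes, seed = 0L) {
  n_genes <- assert_count(n_genes, "n_genes", 1L)
  sprintf("G%06d", seq_len(n_genes))
}

# uniform integer draws on [lo, hi], safe against sample()'s scalar rule
sample_range <- function(lo, hi, n) {
  if (lo == hi) rep(as.integer(lo), n)
  else sample(seq.int(lo, hi), n, replace = TRUE)
}

# map linear indices (row-wise over ordered pairs i < j) back to (i, j)
pair_from_index <- function(k, n) {
  counts <- (n - 1):1
  ends <- cumsum(counts)
  i <- findInterval(k - 1, c(0, ends), rightmost.closed = FALSE)
  offs <- c(0, ends)[i]
  j <- i + (k - offs)
  cbind(i, j)
}

#' Generate an Erdos-Renyi interaction network
#'
#' Each unordered gene pair is an edge independently with probability
#' `mean_degree / (n_genes - 1)`; confidences are i.i.d.
#' Beta(a, b) draws.
#'
#' @param universe character vector of gene symbols.
#' @param mean_degree target expected degree, must be `< |universe| - 1`.
#' @param confidence_beta_params Beta shape parameters `c(a, b)`.
#' @param seed integer seed.
#' @return An [interaction_network()] whose nodes are the full universe.
#' @export
generate_network <- function(universe, mean_degree,
                             confidence_beta_params = c(2, 2), seed = 1L) {
  n <- length(universe)
  if (n < 1) stopf("universe must be non-empty")
  if (mean_degree < 0 || (n > 1 && mean_degree >= n - 1) ||
      (n == 1 && mean_degree > 0)) {
    stopf("mean_degree %s infeasible for %d genes", format(mean_degree), n)
  }
  npairs <- as.numeric(n) * (n - 1) / 2
  prob <- if (n > 1) mean_degree / (n - 1) else 0
  edges <- withr::with_seed(seed, {
    keep <- which(stats::runif(npairs) < prob)
    if (length(keep)) {
      ij <- pair_from_index(keep, n)
      conf <- stats::rbeta(length(keep), confidence_beta_params[1],
                           confidence_beta_params[2])
      data.frame(gene_a = universe[ij[, 1]], gene_b = universe[ij[, 2]],
                 confidence = conf, stringsAsFactors = FALSE)
    } else {
      data.frame(gene_a = character(0), gene_b = character(0),
                 confidence = numeric(0))
    }
  })
  interaction_network(edges, nodes = universe)
}

#' Generate random pathway gene sets
#'
#' @param universe character vector of gene symbols.
#' @param n_pathways number of pathways.
#' @param size_range inclusive integer range of pathway sizes; sizes are
#'   uniform on the range, members uniform subsets of the universe.
#' @param seed integer seed.
#' @return A [pathway_collection()] with ids `PW0001`, ...
#' @export
generate_pathways <- function(universe, n_pathways, size_range, seed = 1L) {
  n_pathways <- assert_count(n_pathways, "n_pathways", 0L)
  if (length(size_range) != 2L || size_range[1] > size_range[2]) {
    stopf("size_range must be a non-empty range")
  }
  if (size_range[2] > length(universe)) {
    stopf("size_range exceeds universe size %d", length(universe))
  }
  if (n_pathways == 0L) {
    return(pathway_collection(stats::setNames(list(), character(0))))
  }
  ids <- sprintf("PW%04d", seq_len(n_pathways))
  genes <- withr::with_seed(seed, {
    sizes <- sample_range(size_range[1], size_range[2], n_pathways)
    lapply(sizes, function(s) sample(universe, s))
  })
  pathway_collection(stats::setNames(genes, ids),
                     stats::setNames(sprintf("synthetic pathway %d",
                                             seq_len(n_pathways)), ids))
}

#' Plant direct seed-to-pathway edges
#'
#' Adds (or raises to `planted_confidence`) edges from `seed_gene` to a
#' uniformly chosen `ceiling(planted_fraction * |pathway|)` subset of the
#' pathway members, leaving all other edges untouched. Planting twice with
#' the same arguments is idempotent.
#'
#' @param network an [interaction_network()].
#' @param seed_gene gene receiving the planted neighbors; must be a node.
#' @param pathway character vector of pathway member genes.
#' @param planted_fraction fraction of the pathway to wire to the seed.
#' @param planted_confidence confidence of planted edges.
#' @param seed integer seed for the member subset choice.
#' @return The modified [interaction_network()].
#' @export
plant_signal <- function(network, seed_gene, pathway, planted_fraction,
                         planted_confidence = 0.9, seed = 1L) {
  if (!(seed_gene %in% network$nodes)) {
    stopf("seed gene '%s' is not a network node", seed_gene)
  }
  pathway <- sort(unique(as.character(pathway)))
  if (!length(pathway)) stopf("pathway must be non-empty")
  assert_prob(planted_fraction, "planted_fraction")
  assert_prob(planted_confidence, "planted_confidence")
  k <- ceiling(planted_fraction * length(pathway))
  if (k == 0) return(network)
  targets <- withr::with_seed(seed, sample(pathway, k))
  targets <- setdiff(targets, seed_gene)
  if (!length(targets)) return(network)
  a <- pmin(seed_gene, targets)
  b <- pmax(seed_gene, targets)
  edges <- network$edges
  key <- paste(edges$gene_a, edges$gene_b, sep = "\r")
  newkey <- paste(a, b, sep = "\r")
  hit <- match(newkey, key)
  present <- !is.na(hit)
  edges$confidence[hit[present]] <- pmax(edges$confidence[hit[present]],
                                         planted_confidence)
  if (any(!present)) {
    edges <- rbind(edges, data.frame(gene_a = a[!present], gene_b = b[!present],
                                     confidence = planted_confidence,
                                     stringsAsFactors = FALSE))
  }
  interaction_network(edges, nodes = network$nodes)
}

#' Generate a complete synthetic study bundle
#'
#' Composes universe, network, pathways, disease catalog, seed genes and
#' planted truth pairs. Truth diseases carry category "nervous"; non-truth
#' diseases alternate "metabolic" and "null". For each truth pair
#' (seed gene, disease), every pathway of that disease receives
#' [plant_signal()] from that seed. Sub-seeds are derived deterministically
#' from `master_seed` by component, so the bundle is reproducible
#' bit-for-bit.
#'
#' @param config a [synthetic_config()].
#' @return An object of class `study_bundle` with elements `network`,
#'   `pathways`, `catalog`, `seed_genes`, `truth` (data frame with columns
#'   `seed_gene`, `disease`), `config`, `master_seed`.
#' @export
generate_study <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  ms <- config$master_seed
  universe <- generate_universe(config$n_genes, derive_seed(ms, 1L))
  network <- generate_network(universe, config$mean_degree,
                              config$confidence_beta_params,
                              derive_seed(ms, 2L))
  pathways <- generate_pathways(universe, config$n_pathways,
                                config$pathway_size_range,
                                derive_seed(ms, 3L))
  seed_genes <- withr::with_seed(derive_seed(ms, 4L),
                                 sort(sample(universe, config$n_seeds)))

  dnames <- sprintf("D%02d", seq_len(config$n_diseases))
  # Pathway groups are kept disjoint across diseases whenever the pathway
  # pool is large enough (and truth-disease pathways are never reused), so
  # planted signal cannot leak into non-truth diseases.
  diseases <- withr::with_seed(derive_seed(ms, 5L), {
    nd <- config$n_diseases
    rng <- config$pathways_per_disease_range
    sizes <- if (nd > 0) sample_range(rng[1], rng[2], nd) else integer(0)
    pool <- sample(pathway_ids(pathways))
    n_truth <- config$n_truth_diseases
    if (sum(sizes[seq_len(n_truth)]) > length(pool)) {
      stopf("not enough pathways for disjoint truth-disease groups")
    }
    out <- vector("list", nd)
    used <- 0L
    for (i in seq_len(nd)) {
      if (used + sizes[i] <= length(pool)) {
        out[[i]] <- pool[used + seq_len(sizes[i])]
        used <- used + sizes[i]
      } else {
        # pool exhausted: non-truth diseases may reuse unplanted pathways
        truth_pw <- unique(unlist(out[seq_len(n_truth)]))
        out[[i]] <- sample(setdiff(pathway_ids(pathways), truth_pw), sizes[i])
      }
    }
    out
  })
  names(diseases) <- dnames
  category <- rep(c("metabolic", "null"),
                  length.out = max(0L, config$n_diseases - config$n_truth_diseases))
  category <- stats::setNames(
    c(rep("nervous", config$n_truth_diseases), category), dnames)
  catalog <- disease_catalog(diseases, category, pathways)

  truth_diseases <- dnames[seq_len(config$n_truth_diseases)]
  truth <- withr::with_seed(derive_seed(ms, 6L), {
    do.call(rbind, c(list(data.frame(seed_gene = character(0),
                                     disease = character(0))),
      lapply(truth_diseases, function(d) {
        data.frame(seed_gene = sort(sample(seed_genes, config$seeds_per_truth)),
                   disease = d, stringsAsFactors = FALSE)
      })))
  })

  if (nrow(truth)) {
    for (i in seq_len(nrow(truth))) {
      pws <- catalog$diseases[[truth$disease[i]]]
      for (j in seq_along(pws)) {
        network <- plant_signal(network, truth$seed_gene[i],
                                pathways$genes[[pws[j]]],
                                config$planted_fraction,
                                config$planted_confidence,
                                derive_seed(ms, 7L, paste(i, j)))
      }
    }
  }

  structure(list(network = network, pathways = pathways, catalog = catalog,
                 seed_genes = seed_genes, truth = truth, config = config,
                 master_seed = ms),
            class = "study_bundle")
}

#' @export
print.study_bundle <- function(x, ...) {
  cat(sprintf(paste0("study_bundle: %d genes, %d edges, %d pathways, ",
                     "%d diseases, %d seeds, %d truth pairs (master seed %d)\n"),
              length(x$network$nodes), nrow(x$network$edges),
              length(x$pathways$genes), length(x$catalog$diseases),
              length(x$seed_genes), nrow(x$truth), x$master_seed))
  invisible(x)
}
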
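# End-to-end pipeline: (simulate | load files) -> extract interactomes ->
# empirical enrichment -> disease scoring -> key genes -> artifacts.

#' Pipeline run configuration
#'
#' Exactly one of `synthetic` (a [synthetic_config()]) or the file inputs
#' (`network_path`, `gmt_path`, `disease_map_path`, `seeds_path`) must be
#' provided.
#'
#' @param network_path STRING-style edge-list TSV.
#' @param gmt_path GMT pathway file.
#' @param disease_map_path disease-to-pathway TSV.
#' @param seeds_path seed-gene spec TSV (see [read_seed_specs()]).
#' @param synthetic a [synthetic_config()] replacing all file inputs.
#' @param universe background policy: "network" (all network nodes) or
#'   "union" (network nodes plus all pathway genes).
#' @param n_null null sets per interactome.
#' @param zero_floor zero replacement floor; NULL picks
#'   [default_zero_floor()] of `n_null`.
#' @param jaccard_threshold Jaccard cutoff for merging near-duplicate
#'   interactomes.
#' @param size_window target interactome size window for auto-tuned seeds.
#' @param min_significance optional empirical-p cutoff for key-gene
#'   counting (NULL counts all pairs).
#' @param master_seed integer master seed for all resampling.
#' @param outdir output directory for artifacts.
#' @param score_scale score dialect passed to [read_network()].
#' @return An object of class `run_config`.
#' @export
run_config <- function(network_path = NULL, gmt_path = NULL,
                       disease_map_path = NULL, seeds_path = NULL,
                       synthetic = NULL,
                       universe = c("network", "union"),
                       n_null = 1000L, zero_floor = NULL,
                       jaccard_threshold = 0.8,
                       size_window = c(100, 600),
                       min_significance = NULL,
                       master_seed = 1L, outdir = "lisindex_out",
                       score_scale = "auto") {
  universe <- match.arg(universe)
  paths <- list(network_path = network_path, gmt_path = gmt_path,
                disease_map_path = disease_map_path, seeds_path = seeds_path)
  have_files <- !vapply(paths, is.null, TRUE)
  if (!is.null(synthetic)) {
    stopifnot(inherits(synthetic, "synthetic_config"))
    if (any(have_files)) {
      stopf("provide either file inputs or a synthetic config, not both")
    }
  } else {
    if (!all(have_files)) {
      stopf("missing input path(s): %s",
            paste(names(paths)[!have_files], collapse = ", "))
    }
    for (p in paths) {
      if (!file.exists(p)) stopf("input file not found: %s", p)
    }
  }
  n_null <- assert_count(n_null, "n_null", 1L)
  if (is.null(zero_floor)) zero_floor <- default_zero_floor(n_null)
  if (zero_floor <= 0 || zero_floor > 1) stopf("zero_floor must lie in (0, 1]")
  if (jaccard_threshold <= 0 || jaccard_threshold > 1) {
    stopf("jaccard_threshold must lie in (0, 1]")
  }
  if (length(size_window) != 2L || size_window[1] > size_window[2]) {
    stopf("size_window must be a non-empty interval")
  }
  if (!is.null(min_significance)) assert_prob(min_significance, "min_significance")
  structure(c(paths,
              list(synthetic = synthetic, universe = universe,
                   n_null = n_null, zero_floor = zero_floor,
                   jaccard_threshold = jaccard_threshold,
                   size_window = as.numeric(size_window),
                   min_significance = min_significance,
                   master_seed = as.integer(master_seed),
                   outdir = outdir, score_scale = score_scale)),
            class = "run_config")
}

#' Read per-seed interactome specs
#'
#' TSV without header: `gene<TAB>threshold<TAB>order`. `threshold` and
#' `order` may both be the literal string `auto`, in which case the spec is
#' tuned to the configured size window at run time.
#'
#' @param path file path.
#' @return Data frame with columns `gene`, `threshold`, `order` (`NA` for
#'   auto rows).
#' @export
read_seed_specs <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stopf("seed spec file is empty")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 3L)
  if (length(bad)) stopf("seed spec row %d: expected 3 columns", bad[1])
  gene <- vapply(fields, `[[`, "", 1L)
  thr <- vapply(fields, `[[`, "", 2L)
  ord <- vapply(fields, `[[`, "", 3L)
  auto <- thr == "auto" | ord == "auto"
  data.frame(gene = gene,
             threshold = ifelse(auto, NA, suppressWarnings(as.numeric(thr))),
             order = ifelse(auto, NA, suppressWarnings(as.integer(ord))),
             stringsAsFactors = FALSE)
}

#' Write per-seed interactome specs
#' @param specs data frame as returned by [read_seed_specs()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_seed_specs <- function(specs, path) {
  lines <- vapply(seq_len(nrow(specs)), function(i) {
    if (is.na(specs$threshold[i]) || is.na(specs$order[i])) {
      paste(specs$gene[i], "auto", "auto", sep = "\t")
    } else {
      paste(specs$gene[i], num_chr(specs$threshold[i]), specs$order[i],
            sep = "\t")
    }
  }, "")
  writeLines(lines, path)
  invisible(path)
}

build_universe <- function(network, pathways, policy) {
  switch(policy,
         network = network$nodes,
         union = sort(unique(c(network$nodes, unlist(pathways$genes)))),
         stopf("unknown universe policy '%s'", policy))
}

extract_all <- function(network, seed_specs, size_window, jaccard_threshold) {
  interactomes <- lapply(seq_len(nrow(seed_specs)), function(i) {
    g <- seed_specs$gene[i]
    if (is.na(seed_specs$threshold[i]) || is.na(seed_specs$order[i])) {
      tuned <- tune_interactome(network, g, size_window)
      if (!tuned$in_window) {
        message(sprintf(
          "interactome '%s' flagged: size %d outside window [%g, %g]",
          g, length(tuned$interactome$members), size_window[1], size_window[2]))
      }
      tuned$interactome
    } else {
      extract_interactome(network,
                          interactome_spec(g, seed_specs$threshold[i],
                                           seed_specs$order[i]))
    }
  })
  merge_similar(interactomes, jaccard_threshold)
}

#' Run the full pipeline
#'
#' Loads or simulates the study inputs, extracts and merges interactomes,
#' computes the empirical enrichment matrix, scores and ranks diseases,
#' scores key genes, and writes every artifact (plus
#' `category_summary.tsv` and `interactomes.tsv`) under `config$outdir`.
#' All randomness derives from `config$master_seed`, so two runs with the
#' same config produce byte-identical outputs.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with `interactomes`, `matrix`, `scores`,
#'   `ranking`, `summary`, `gene_scores`, `outdir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$synthetic)) {
    message("stage simulate: generating synthetic study bundle")
    bundle <- generate_study(config$synthetic)
    network <- bundle$network
    pathways <- bundle$pathways
    catalog <- bundle$catalog
    seed_specs <- data.frame(gene = bundle$seed_genes,
                             threshold = NA_real_, order = NA_integer_,
                             stringsAsFactors = FALSE)
  } else {
    message("stage load: reading input files")
    network <- read_network(config$network_path, config$score_scale)
    pathways <- read_gmt(config$gmt_path)
    catalog <- read_disease_map(config$disease_map_path, pathways)
    seed_specs <- read_seed_specs(config$seeds_path)
  }

  message(sprintf("stage extract: %d seed gene(s), window [%g, %g], jaccard %g",
                  nrow(seed_specs), config$size_window[1],
                  config$size_window[2], config$jaccard_threshold))
  interactomes <- extract_all(network, seed_specs, config$size_window,
                              config$jaccard_threshold)
  message(sprintf("stage extract: %d interactome(s) after merging",
                  length(interactomes)))

  universe <- build_universe(network, pathways, config$universe)
  message(sprintf("stage enrich: universe %d genes, n_null %d, master seed %d",
                  length(universe), config$n_null, config$master_seed))
  matrix <- enrich_matrix(interactomes, pathways, universe,
                          n_null = config$n_null,
                          master_seed = config$master_seed)

  message(sprintf("stage score: %d disease(s), zero floor %g",
                  length(catalog$diseases), config$zero_floor))
  scores <- score_all_diseases(matrix, catalog, config$zero_floor)
  ranking <- rank_diseases(scores, catalog)
  summary <- category_summary(scores, catalog)

  message("stage keygenes: scoring cross-section genes")
  gene_scores <- key_gene_scores(interactomes, catalog, pathways, matrix,
                                 config$min_significance)

  cfg_json <- list(
    inputs = if (is.null(config$synthetic)) {
      list(network = config$network_path, gmt = config$gmt_path,
           disease_map = config$disease_map_path, seeds = config$seeds_path)
    } else {
      unclass(config$synthetic)
    },
    universe = config$universe, n_null = config$n_null,
    zero_floor = config$zero_floor,
    jaccard_threshold = config$jaccard_threshold,
    size_window = config$size_window,
    min_significance = config$min_significance,
    master_seed = config$master_seed,
    interactomes = lapply(interactomes, function(x) {
      list(name = x$name, size = length(x$members),
           spec = if (identical(x$spec, "merged")) "merged" else unclass(x$spec))
    }))

  write_results(matrix, ranking, gene_scores, catalog, config$outdir,
                run_config = cfg_json)
  sm <- summary
  for (cn in c("min", "q1", "median", "q3", "max")) sm[[cn]] <- num_chr(sm[[cn]])
  write_tsv(sm, file.path(config$outdir, "category_summary.tsv"))
  write_interactomes(interactomes,
                     file.path(config$outdir, "interactomes.tsv"))

  invisible(list(interactomes = interactomes, matrix = matrix,
                 scores = scores, ranking = ranking, summary = summary,
                 gene_scores = gene_scores, outdir = config$outdir))
}

#' Write interactomes as a long-format TSV
#' @param interactomes list of `interactome` objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_interactomes <- function(interactomes, path) {
  df <- do.call(rbind, lapply(interactomes, function(x) {
    data.frame(interactome = x$name, gene = x$members,
               stringsAsFactors = FALSE)
  }))
  if (is.null(df)) df <- data.frame(interactome = character(0),
                                    gene = character(0))
  write_tsv(df, path)
}

#' Read interactomes from a long-format TSV
#' @param path file written by [write_interactomes()].
#' @return List of `interactome` objects (spec recorded as "file").
#' @export
read_interactomes <- function(path) {
  df <- read_tsv(path, colClasses = "character")
  if (!all(c("interactome", "gene") %in% names(df))) {
    stopf("interactome file must have columns 'interactome' and 'gene'")
  }
  nms <- unique(df$interactome)
  lapply(nms, function(nm) {
    new_interactome(nm, df$gene[df$interactome == nm], spec = "file")
  })
}

#' Read a long-format enrichment table back into a matrix
#'
#' Inverse of the `enrichment_long.tsv` artifact; `null_p` distributions
#' are not part of the file and are absent from the result.
#'
#' @param path file path.
#' @param n_null null-set count recorded with the matrix (used for the
#'   default zero floor downstream); inferred as the reciprocal of the
#'   smallest nonzero empirical p when NULL.
#' @return An `enrichment_matrix` object without `null_p`.
#' @export
read_enrichment_long <- function(path, n_null = NULL) {
  df <- read_tsv(path)
  need <- c("interactome", "pathway", "uncorrected_p", "empirical_p")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("enrichment file missing column '%s'", miss[1])
  rows <- unique(df$interactome)
  cols <- unique(df$pathway)
  shape <- function(v) {
    m <- matrix(NA_real_, length(rows), length(cols),
                dimnames = list(rows, cols))
    m[cbind(match(df$interactome, rows), match(df$pathway, cols))] <- v
    if (anyNA(m)) stopf("enrichment file is not a complete matrix")
    m
  }
  if (is.null(n_null)) {
    nz <- df$empirical_p[df$empirical_p > 0]
    n_null <- if (length(nz)) as.integer(round(1 / min(nz))) else 1000L
  }
  structure(list(empirical_p = shape(df$empirical_p),
                 uncorrected_p = shape(df$uncorrected_p),
                 overlap = if ("overlap" %in% names(df)) shape(df$overlap) else NULL,
                 null_p = NULL, n_null = as.integer(n_null), seed = NA_integer_),
            class = "enrichment_matrix")
}
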
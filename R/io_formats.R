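# Domain containers and readers/writers for the external file formats.
#
# All downstream modules consume and produce only the in-memory types built
# here: interaction_network, pathway_collection, disease_catalog.

#' Construct an interaction network
#'
#' An `interaction_network` is an undirected weighted graph over gene symbols
#' with one confidence score in \[0, 1\] per unordered gene pair. Self-loops
#' and duplicate pairs are disallowed; `nodes` may contain isolated genes in
#' addition to edge endpoints.
#'
#' @param edges data frame with character columns `gene_a`, `gene_b` and a
#'   numeric `confidence` column in \[0, 1\].
#' @param nodes optional character vector of node symbols; defaults to the
#'   set of edge endpoints. Must be a superset of the endpoints.
#' @return An object of class `interaction_network` with elements `edges`
#'   (canonicalized: `gene_a < gene_b`, sorted) and `nodes` (sorted, unique).
#' @export
interaction_network <- function(edges, nodes = NULL) {
  stopifnot(is.data.frame(edges),
            all(c("gene_a", "gene_b", "confidence") %in% names(edges)))
  ga <- as.character(edges$gene_a)
  gb <- as.character(edges$gene_b)
  conf <- as.numeric(edges$confidence)
  if (any(!nzchar(ga)) || any(!nzchar(gb))) stopf("empty gene symbol in edges")
  if (any(ga == gb)) stopf("self-loops are not allowed")
  assert_prob(conf, "edge confidence")
  a <- pmin(ga, gb)
  b <- pmax(ga, gb)
  key <- paste(a, b, sep = "\r")
  if (anyDuplicated(key)) stopf("duplicate edges for the same gene pair")
  endpoints <- unique(c(a, b))
  if (is.null(nodes)) {
    nodes <- endpoints
  } else {
    nodes <- unique(as.character(nodes))
    missing <- setdiff(endpoints, nodes)
    if (length(missing)) {
      stopf("edge endpoints not in nodes: %s",
            paste(utils::head(missing, 5), collapse = ", "))
    }
  }
  o <- order(a, b)
  structure(
    list(edges = data.frame(gene_a = a[o], gene_b = b[o],
                            confidence = conf[o], stringsAsFactors = FALSE),
         nodes = sort(nodes)),
    class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("interaction_network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Construct a pathway collection
#'
#' @param genes named list of character vectors (pathway id -> member genes).
#' @param description optional named character vector of descriptions,
#'   aligned with `names(genes)`.
#' @return An object of class `pathway_collection`.
#' @export
pathway_collection <- function(genes, description = NULL) {
  stopifnot(is.list(genes))
  ids <- names(genes)
  if (is.null(ids) && length(genes) == 0L) ids <- character(0)
  if (length(genes) && (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids)))) {
    stopf("pathway ids must be unique non-empty names")
  }
  genes <- lapply(genes, function(g) sort(unique(as.character(g))))
  if (any(lengths(genes) == 0L) && length(genes)) stopf("pathway gene sets must be non-empty")
  if (is.null(description)) {
    description <- stats::setNames(rep("", length(ids)), ids)
  } else {
    description <- stats::setNames(as.character(description[ids]), ids)
  }
  structure(list(genes = genes, description = description),
            class = "pathway_collection")
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat(sprintf("pathway_collection: %d pathways (sizes %s)\n", length(x$genes),
              if (length(x$genes)) paste(range(lengths(x$genes)), collapse = "-") else "-"))
  invisible(x)
}

pathway_ids <- function(pathways) names(pathways$genes)

#' Construct a disease catalog
#'
#' Groups pathway ids under disease names and attaches one category label
#' per disease (e.g. "nervous", "metabolic", "null") used by the category
#' summary.
#'
#' @param diseases named list of character vectors (disease -> pathway ids).
#' @param category named character vector (disease -> category label).
#' @param pathways companion [pathway_collection()] used to enforce
#'   referential integrity.
#' @return An object of class `disease_catalog`.
#' @export
disease_catalog <- function(diseases, category, pathways) {
  stopifnot(is.list(diseases))
  nms <- names(diseases)
  if (length(diseases) && (is.null(nms) || anyDuplicated(nms))) {
    stopf("disease names must be unique")
  }
  if (any(lengths(diseases) == 0L)) stopf("each disease needs at least one pathway")
  known <- pathway_ids(pathways)
  for (d in nms) {
    bad <- setdiff(diseases[[d]], known)
    if (length(bad)) {
      stopf("disease '%s' references unknown pathway id(s): %s",
            d, paste(bad, collapse = ", "))
    }
  }
  if (length(diseases) && !all(nms %in% names(category))) {
    stopf("every disease needs a category label")
  }
  category <- stats::setNames(as.character(category[nms]), nms)
  structure(list(diseases = diseases, category = category),
            class = "disease_catalog")
}

#' @export
print.disease_catalog <- function(x, ...) {
  cat(sprintf("disease_catalog: %d diseases, categories: %s\n",
              length(x$diseases),
              paste(sort(unique(x$category)), collapse = ", ")))
  invisible(x)
}

# ---------------------------------------------------------------------------
# readers

#' Read a STRING-style weighted edge list
#'
#' Parses a whitespace- or tab-delimited edge list `geneA geneB score`. An
#' optional header line is detected by a non-numeric third column. Two score
#' dialects are supported: STRING's integer combined scores 0-999
#' (`string999`, divided by 1000) and unit-interval reals (`unit`). With
#' `score_scale = "auto"` the string999 dialect is chosen iff every score is
#' an integer greater than 1. Duplicate pairs keep the maximum confidence;
#' self-loops are dropped with a warning.
#'
#' @param path file path.
#' @param score_scale one of "auto", "unit", "string999".
#' @return An [interaction_network()].
#' @export
read_network <- function(path, score_scale = c("auto", "unit", "string999")) {
  score_scale <- match.arg(score_scale)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(interaction_network(data.frame(gene_a = character(0),
                                          gene_b = character(0),
                                          confidence = numeric(0))))
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  ncols <- lengths(fields)
  bad <- which(ncols != 3L)
  start <- 1L
  # header detection: first line whose third column is not numeric
  if (ncols[1] == 3L && is.na(suppressWarnings(as.numeric(fields[[1]][3])))) {
    start <- 2L
  }
  bad <- bad[bad >= start]
  if (length(bad)) {
    stopf("malformed edge line %d: expected 3 columns, got %d",
          bad[1], ncols[bad[1]])
  }
  if (start > length(fields)) {
    return(interaction_network(data.frame(gene_a = character(0),
                                          gene_b = character(0),
                                          confidence = numeric(0))))
  }
  fields <- fields[start:length(fields)]
  ga <- vapply(fields, `[[`, "", 1L)
  gb <- vapply(fields, `[[`, "", 2L)
  sc <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (anyNA(sc)) {
    stopf("non-numeric score on edge line %d", which(is.na(sc))[1] + start - 1L)
  }
  if (score_scale == "auto") {
    score_scale <- if (length(sc) && all(sc == floor(sc)) && all(sc > 1)) {
      "string999"
    } else "unit"
  }
  if (score_scale == "string999") sc <- sc / 1000
  if (any(sc < 0 | sc > 1)) {
    stopf("score outside [0, 1] after scaling on edge line %d",
          which(sc < 0 | sc > 1)[1] + start - 1L)
  }
  loops <- ga == gb
  if (any(loops)) {
    warning(sprintf("dropped %d self-loop(s)", sum(loops)), call. = FALSE)
    ga <- ga[!loops]; gb <- gb[!loops]; sc <- sc[!loops]
  }
  a <- pmin(ga, gb); b <- pmax(ga, gb)
  key <- paste(a, b, sep = "\r")
  conf <- tapply(sc, key, max)
  first <- !duplicated(key)
  interaction_network(data.frame(
    gene_a = a[first], gene_b = b[first],
    confidence = as.numeric(conf[key[first]]),
    stringsAsFactors = FALSE))
}

#' Read a GMT pathway file
#'
#' Each line is `id<TAB>description<TAB>gene1<TAB>gene2...`. Genes are
#' deduplicated within a pathway; pathway ids must be unique.
#'
#' @param path file path.
#' @return A [pathway_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(pathway_collection(stats::setNames(list(), character(0))))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) stopf("GMT line %d has fewer than 3 fields", short[1])
  ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(ids)) {
    stopf("duplicate pathway id '%s' in GMT", ids[duplicated(ids)][1])
  }
  genes <- stats::setNames(lapply(fields, function(f) f[-(1:2)]), ids)
  descs <- stats::setNames(vapply(fields, `[[`, "", 2L), ids)
  pathway_collection(genes, descs)
}

#' Read a disease-to-pathway mapping
#'
#' TSV with one row `disease<TAB>category<TAB>pathway_id` per (disease,
#' pathway) assignment; no header. Rows are grouped by disease and checked
#' against the companion pathway collection.
#'
#' @param path file path.
#' @param pathways the [pathway_collection()] the mapping refers to.
#' @return A [disease_catalog()].
#' @export
read_disease_map <- function(path, pathways) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(disease_catalog(stats::setNames(list(), character(0)),
                           character(0), pathways))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 3L)
  if (length(bad)) stopf("disease map row %d: expected 3 columns", bad[1])
  disease <- vapply(fields, `[[`, "", 1L)
  category <- vapply(fields, `[[`, "", 2L)
  pw <- vapply(fields, `[[`, "", 3L)
  known <- pathway_ids(pathways)
  bad <- which(!(pw %in% known))
  if (length(bad)) {
    stopf("disease map row %d references unknown pathway id '%s'",
          bad[1], pw[bad[1]])
  }
  for (d in unique(disease)) {
    cats <- unique(category[disease == d])
    if (length(cats) > 1L) {
      stopf("disease '%s' has conflicting categories: %s",
            d, paste(cats, collapse = ", "))
    }
  }
  diseases <- lapply(split(pw, disease), function(p) unique(p))
  cat_by_disease <- vapply(split(category, disease), `[[`, "", 1L)
  disease_catalog(diseases, cat_by_disease, pathways)
}

# ---------------------------------------------------------------------------
# writers

#' Write an interaction network as a unit-dialect edge list
#' @param network an [interaction_network()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  df <- network$edges
  lines <- paste(df$gene_a, df$gene_b, num_chr(df$confidence), sep = "\t")
  writeLines(c("gene_a\tgene_b\tcombined_score", lines), path)
  invisible(path)
}

#' Write a pathway collection in GMT format
#' @param pathways a [pathway_collection()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(pathways, path) {
  ids <- pathway_ids(pathways)
  lines <- vapply(ids, function(id) {
    paste(c(id, pathways$description[[id]], pathways$genes[[id]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a disease catalog as a disease-map TSV
#' @param catalog a [disease_catalog()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_disease_map <- function(catalog, path) {
  lines <- unlist(lapply(names(catalog$diseases), function(d) {
    paste(d, catalog$category[[d]], catalog$diseases[[d]], sep = "\t")
  }))
  writeLines(as.character(lines), path)
  invisible(path)
}

sanitize_filename <- function(x) gsub("[^A-Za-z0-9._-]+", "_", x)

#' Write all pipeline result artifacts
#'
#' Writes five artifacts under `outdir`: the long-format enrichment table
#' (`enrichment_long.tsv`), one wide empirical-p heatmap TSV per disease
#' (`heatmap_<disease>.tsv`), the disease score table
#' (`disease_scores.tsv`), the key-gene score table (`gene_scores.tsv`) and
#' a JSON snapshot of every parameter and seed (`run_config.json`).
#'
#' @param matrix an [enrich_matrix()] result.
#' @param scores disease ranking data frame from [rank_diseases()].
#' @param genes gene score table from [gene_score_table()].
#' @param catalog the [disease_catalog()] (needed for the per-disease
#'   heatmaps).
#' @param outdir output directory, created if absent.
#' @param run_config named list of parameters/seeds to snapshot.
#' @return Character vector of written paths, invisibly.
#' @export
write_results <- function(matrix, scores, genes, catalog, outdir,
                          run_config = list()) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  paths <- character(0)

  long <- enrichment_long(matrix)
  p <- file.path(outdir, "enrichment_long.tsv")
  long$uncorrected_p <- num_chr(long$uncorrected_p)
  long$empirical_p <- num_chr(long$empirical_p)
  write_tsv(long, p)
  paths <- c(paths, p)

  for (d in names(catalog$diseases)) {
    pw <- catalog$diseases[[d]]
    wide <- matrix$empirical_p[, pw, drop = FALSE]
    cells <- matrix(num_chr(wide), nrow = nrow(wide), dimnames = dimnames(wide))
    df <- data.frame(interactome = rownames(wide), cells,
                     check.names = FALSE, stringsAsFactors = FALSE)
    p <- file.path(outdir, paste0("heatmap_", sanitize_filename(d), ".tsv"))
    write_tsv(df, p)
    paths <- c(paths, p)
  }

  p <- file.path(outdir, "disease_scores.tsv")
  out <- data.frame(rank = scores$rank, disease = scores$disease,
                    category = scores$category,
                    p_mean = num_chr(scores$p_mean),
                    sensitivity_index = num_chr(scores$sensitivity_index),
                    stringsAsFactors = FALSE)
  write_tsv(out, p)
  paths <- c(paths, p)

  p <- file.path(outdir, "gene_scores.tsv")
  gout <- genes
  if (nrow(gout)) {
    num <- setdiff(names(gout), "gene")
    for (cn in num) gout[[cn]] <- sprintf("%.2f", gout[[cn]])
  }
  write_tsv(gout, p)
  paths <- c(paths, p)

  p <- file.path(outdir, "run_config.json")
  jsonlite::write_json(run_config, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  paths <- c(paths, p)
  invisible(paths)
}
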
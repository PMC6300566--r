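#' @keywords internal
"_PACKAGE"

# Deterministic sub-seed derivation: master seed plus a fixed per-component
# offset, optionally mixed with a string key (e.g. an interactome name).
# Result always lies in [1, 2^31 - 2] so it is a valid set.seed() argument.
derive_seed <- function(master_seed, offset = 0L, key = NULL) {
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(master_seed) %% m
  h <- (h + 1000003 * (as.numeric(offset) %% m)) %% m
  if (!is.null(key)) {
    for (ch in utf8ToInt(as.character(key))) h <- (h * 31 + ch) %% m
  }
  as.integer(h %% (m - 1) + 1)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stopf("%s must lie in [0, 1]", what)
  }
  invisible(x)
}

assert_count <- function(x, what, min = 0L) {
  if (length(x) != 1L || !is.finite(x) || x != floor(x) || x < min) {
    stopf("%s must be a single integer >= %d", what, min)
  }
  invisible(as.integer(x))
}

# Full-precision numeric formatting: 17 significant digits round-trips
# IEEE doubles exactly, so file-mediated and in-memory pipelines agree.
num_chr <- function(x) {
  out <- formatC(x, digits = 17, format = "g", flag = "")
  trimws(out)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}
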
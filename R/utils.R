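# Shared internal helpers: logging, seed streams, TSV matrix I/O.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
new_log <- function() {
  env <- new.env(parent = emptyenv())
  env$lines <- character()
  env
}

# Collects lines into `log` (if supplied) and echoes to stderr when
# options(bcmrank.verbose = TRUE).
log_line <- function(log, ...) {
  msg <- paste0(...)
  if (!is.null(log)) log$lines <- c(log$lines, msg)
  if (isTRUE(getOption("bcmrank.verbose", FALSE))) message(msg)
  invisible(msg)
}

# Deterministic per-stage sub-seed derived from a single top-level seed.
# Kept strictly below 2^31 - 1 so it is always a valid integer seed.
substream <- function(seed, offset) {
  as.integer((as.numeric(seed) %% 2147483647 + 9973 * (offset %% 100000)) %% 2147483647)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# TSV matrix layout: first column = gene id, header = sample ids.
read_tsv_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("matrix file needs a gene-id column plus >= 1 sample column: ", path)
  genes <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- genes
  mat
}

write_tsv_matrix <- function(mat, path, id_col = "gene_id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(id_col, colnames(mat))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# rowVars without a matrixStats dependency
row_vars <- function(mat) {
  n <- ncol(mat)
  if (n < 2) return(rep(NA_real_, nrow(mat)))
  m <- rowMeans(mat)
  rowSums((mat - m)^2) / (n - 1)
}

is_wholenumber <- function(x, tol = 1e-8) {
  is.finite(x) & abs(x - round(x)) < tol
}
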
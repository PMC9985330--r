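#' Construct a single-study expression experiment
#'
#' An `experiment` holds one study's gene-by-sample expression matrix together
#' with its per-sample metadata and a technology tag. Microarray matrices are
#' expected on a log-normalized intensity scale; RNA-seq matrices must contain
#' non-negative integer counts.
#'
#' @param matrix numeric gene-by-sample matrix with unique row (gene) and
#'   column (sample) names.
#' @param sample_meta data.frame of per-sample biological covariates. Either
#'   row names are sample identifiers, or a `sample_id` column is present.
#'   Every matrix column must be covered.
#' @param technology `"microarray"` or `"rnaseq"`.
#' @param id short study label (used as the batch label after merging).
#' @return an object of class `experiment`.
#' @export
experiment <- function(matrix, sample_meta, technology = c("microarray", "rnaseq"),
                       id = "experiment") {
  technology <- match.arg(technology)
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop("matrix must be a numeric matrix")
  if (is.null(rownames(matrix)) || is.null(colnames(matrix)))
    stop("matrix needs gene row names and sample column names")
  dup_g <- unique(rownames(matrix)[duplicated(rownames(matrix))])
  if (length(dup_g))
    stop("duplicate gene ids: ", paste(utils::head(dup_g, 5), collapse = ", "))
  dup_s <- unique(colnames(matrix)[duplicated(colnames(matrix))])
  if (length(dup_s))
    stop("duplicate sample ids: ", paste(utils::head(dup_s, 5), collapse = ", "))
  if (anyNA(matrix)) stop("matrix contains missing values; drop them upstream")
  if (technology == "rnaseq") {
    if (any(matrix < 0)) stop("negative count in rnaseq matrix")
    if (!all(is_wholenumber(matrix))) stop("non-integer count in rnaseq matrix")
  }

  sample_meta <- as.data.frame(sample_meta, stringsAsFactors = FALSE)
  if ("sample_id" %in% colnames(sample_meta)) {
    rownames(sample_meta) <- as.character(sample_meta$sample_id)
    sample_meta$sample_id <- NULL
  }
  missing <- setdiff(colnames(matrix), rownames(sample_meta))
  if (length(missing))
    stop("samples absent from metadata: ", paste(utils::head(missing, 5), collapse = ", "))
  sample_meta <- sample_meta[colnames(matrix), , drop = FALSE]

  structure(
    list(id = as.character(id), matrix = matrix, sample_meta = sample_meta,
         technology = technology),
    class = "experiment"
  )
}

#' @export
print.experiment <- function(x, ...) {
  cat("<experiment> ", x$id, ": ", nrow(x$matrix), " genes x ", ncol(x$matrix),
      " samples (", x$technology, ")\n", sep = "")
  cat("  covariates: ", paste(colnames(x$sample_meta), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read an experiment from TSV files
#'
#' The matrix file is tab-delimited with the first column holding gene
#' identifiers and the header row holding sample identifiers. The metadata file
#' is tab-delimited with a `sample_id` column plus one column per biological
#' covariate. Gene rows containing any missing value are dropped (the count is
#' logged via a message when `options(bcmrank.verbose = TRUE)`).
#'
#' @param matrix_path path to the expression TSV.
#' @param meta_path path to the sample-metadata TSV.
#' @inheritParams experiment
#' @param log optional internal log collector.
#' @return an [experiment()].
#' @export
read_experiment <- function(matrix_path, meta_path, technology = c("microarray", "rnaseq"),
                            id = NULL, log = NULL) {
  technology <- match.arg(technology)
  if (is.null(id))
    id <- sub("\\.(tsv|txt)$", "", basename(matrix_path))
  df <- utils::read.delim(matrix_path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("matrix file needs a gene-id column plus sample columns")
  genes <- as.character(df[[1]])
  dup <- unique(genes[duplicated(genes)])
  if (length(dup))
    stop("duplicate gene ids in ", matrix_path, ": ",
         paste(utils::head(dup, 5), collapse = ", "))
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- genes

  drop <- rowSums(is.na(mat)) > 0
  if (any(drop)) {
    log_line(log, "read_experiment[", id, "]: dropped ", sum(drop),
             " gene(s) with missing values")
    mat <- mat[!drop, , drop = FALSE]
  }
  if (technology == "rnaseq") {
    if (any(mat < 0)) stop("negative count in rnaseq matrix ", matrix_path)
    if (!all(is_wholenumber(mat))) stop("non-integer count in rnaseq matrix ", matrix_path)
  }

  meta <- utils::read.delim(meta_path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% colnames(meta))
    stop("metadata file must contain a sample_id column: ", meta_path)
  experiment(mat, meta, technology = technology, id = id)
}
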
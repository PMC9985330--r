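# Remove-unwanted-variation with control genes: unwanted factors are the
# leading singular vectors of the (gene-centred) sample-by-control submatrix,
# removed from all genes by ridge regression.

#' Packaged human housekeeping gene symbols
#'
#' A curated list of widely used human housekeeping genes (classical loading
#' controls plus large ribosomal-protein and translation-machinery families),
#' intended as negative-control genes for [correct_naive_ruv()]. Replaceable
#' via the `hk_file` argument.
#'
#' @param hk_file optional path to a one-symbol-per-line replacement list.
#' @return character vector of gene symbols.
#' @export
housekeeping_genes <- function(hk_file = NULL) {
  path <- hk_file %||% system.file("extdata", "housekeeping_human.txt",
                                   package = "bcmrank", mustWork = TRUE)
  genes <- readLines(path)
  genes <- trimws(genes)
  genes[nzchar(genes) & !startsWith(genes, "#")]
}

#' Naive random-factor RUV correction
#'
#' Estimates `k` unwanted factors from control genes and removes them with a
#' ridge-regularized regression. Controls are either the packaged human
#' housekeeping list intersected with the meta-experiment genes
#' (`"housekeeping"`) or the `m` least-variable genes after within-batch
#' centring (`"empirical"`). Genes are mean-centred before factor estimation
#' and the means restored afterwards, so `nu -> Inf` recovers the input.
#'
#' @inheritParams correct_limma
#' @param controls `"empirical"` or `"housekeeping"`.
#' @param k number of unwanted factors (`k <= min(#controls, #samples)`).
#' @param nu ridge coefficient; default `0.01 * mean(singular values)^2` of
#'   the control submatrix.
#' @param pre_quantile quantile-normalize before correcting (the
#'   quantile-combined variants).
#' @param m number of empirical control genes; default
#'   `max(100, 5% of genes)`, capped at the gene count.
#' @param hk_file optional replacement housekeeping list.
#' @return a `correction_result`; `params` records the resolved controls,
#'   `k` and `nu`.
#' @export
correct_naive_ruv <- function(meta, controls = c("empirical", "housekeeping"),
                              k = 2, nu = NULL, pre_quantile = FALSE,
                              m = NULL, hk_file = NULL) {
  controls <- match.arg(controls)
  p <- meta_parts(meta)
  mat <- p$matrix
  if (pre_quantile) mat <- quantile_normalize(mat)
  G <- nrow(mat); S <- ncol(mat)

  if (controls == "housekeeping") {
    ctrl <- intersect(housekeeping_genes(hk_file), rownames(mat))
    if (!length(ctrl))
      stop("no housekeeping genes found in the meta-experiment; ",
           "try controls = 'empirical'")
  } else {
    m <- m %||% max(100, ceiling(0.05 * G))
    m <- min(m, G)
    centred <- mat
    for (b in unique(p$batch)) {
      idx <- which(p$batch == b)
      centred[, idx] <- mat[, idx, drop = FALSE] - rowMeans(mat[, idx, drop = FALSE])
    }
    v <- row_vars(centred)
    ctrl <- rownames(mat)[order(v, rownames(mat))[seq_len(m)]]
  }
  if (k > min(length(ctrl), S))
    stop("k = ", k, " exceeds min(#controls, #samples) = ", min(length(ctrl), S))

  Y <- t(mat)                      # samples x genes
  mu <- colMeans(Y)
  Yc <- sweep(Y, 2, mu)
  C <- Yc[, ctrl, drop = FALSE]
  sv <- svd(C)
  nu <- nu %||% (0.01 * mean(sv$d)^2)
  W <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  alpha <- solve(crossprod(W) + nu * diag(k), crossprod(W, Yc))
  corrected <- t(Yc - W %*% alpha) + mu

  label <- paste0(if (pre_quantile) "Q_" else "", "naiveRandRUV_",
                  if (controls == "housekeeping") "HK" else "empi.controls")
  correction_result(label, corrected, meta,
                    list(controls = controls, n_controls = length(ctrl),
                         k = k, nu = nu, pre_quantile = pre_quantile))
}
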
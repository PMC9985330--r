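#' Linear (limma-style) batch removal
#'
#' Per gene, fits ordinary least squares of expression on an intercept,
#' optional biological-condition indicators, and sum-to-zero batch contrasts,
#' then subtracts the fitted batch component. Sum-to-zero coding keeps each
#' gene's grand mean in place. With a single batch there is no batch contrast
#' and the data are returned unchanged.
#'
#' @param meta a `meta_experiment` (or a plain list with `matrix`, `batch`,
#'   and optionally `bio`).
#' @param preserve_bio if `TRUE`, protect the biological covariate by
#'   including it in the design; requires it not to be confounded with batch.
#' @return a `correction_result`.
#' @export
correct_limma <- function(meta, preserve_bio = FALSE) {
  p <- meta_parts(meta)
  mat <- p$matrix
  batch <- factor(p$batch)

  if (nlevels(batch) < 2) {
    return(correction_result("limma", mat, meta, list(preserve_bio = preserve_bio)))
  }

  Xb <- stats::model.matrix(~ batch,
                            contrasts.arg = list(batch = "contr.sum"))[, -1, drop = FALSE]
  design <- cbind(`(Intercept)` = 1, Xb)
  nb <- ncol(Xb)
  if (preserve_bio) {
    if (is.null(p$bio) || length(unique(p$bio)) < 2)
      stop("preserve_bio requires a biological covariate with >= 2 categories")
    bio <- factor(p$bio)
    Xc <- stats::model.matrix(~ bio)[, -1, drop = FALSE]
    design <- cbind(`(Intercept)` = 1, Xc, Xb)
  }
  if (qr(design)$rank < ncol(design))
    stop("rank-deficient design: batch confounded with biological covariate")

  coef <- solve(crossprod(design), crossprod(design, t(mat)))  # p x G
  batch_cols <- (ncol(design) - nb + 1):ncol(design)
  batch_comp <- t(design[, batch_cols, drop = FALSE] %*% coef[batch_cols, , drop = FALSE])
  correction_result("limma", mat - batch_comp, meta,
                    list(preserve_bio = preserve_bio))
}
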
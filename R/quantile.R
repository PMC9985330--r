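#' Quantile-normalize a gene-by-sample matrix
#'
#' Forces every column onto the same empirical distribution: the reference is
#' the row-wise mean of the per-column order statistics. Tied values within a
#' column receive the mean of the reference values at their tied rank
#' positions, so the map is deterministic.
#'
#' @param mat numeric gene-by-sample matrix with >= 2 columns (a single column
#'   is returned unchanged with a warning).
#' @return a matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(mat) {
  if (ncol(mat) < 2) {
    warning("quantile_normalize: single sample, returning unchanged")
    return(mat)
  }
  ref <- rowMeans(apply(mat, 2, sort))
  out <- apply(mat, 2, function(x) {
    idx <- order(x)
    xs <- x[idx]
    grp <- cumsum(c(TRUE, xs[-1] != xs[-length(xs)]))
    res <- stats::ave(ref, grp, FUN = mean)
    out_col <- numeric(length(x))
    out_col[idx] <- res
    out_col
  })
  dimnames(out) <- dimnames(mat)
  out
}
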
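# Container for one batch-correction method's output.

#' @noRd
correction_result <- function(method, matrix, meta, params = list(),
                              scale = c("log", "counts")) {
  scale <- match.arg(scale)
  stopifnot(identical(dim(matrix), dim(meta$matrix)))
  dimnames(matrix) <- dimnames(meta$matrix)
  if (any(!is.finite(matrix)))
    stop(method, ": corrected matrix contains non-finite values")
  structure(list(method = method, matrix = matrix, params = params, scale = scale),
            class = "correction_result")
}

#' @export
print.correction_result <- function(x, ...) {
  cat("<correction_result> ", x$method, ": ", nrow(x$matrix), " genes x ",
      ncol(x$matrix), " samples (", x$scale, " scale)\n", sep = "")
  invisible(x)
}
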
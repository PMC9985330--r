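# Mutual-nearest-neighbour batch correction: pairs are found between batches
# in cosine-normalized expression space; the pair correction vectors are
# smoothed per target sample with a Gaussian kernel and applied on the
# original (log) scale, so the reference batch is never modified.

#' Find mutual nearest neighbours between two batches
#'
#' A pair (r, t) is mutual when r is among t's `k` nearest reference samples
#' and t is among r's `k` nearest target samples (Euclidean distance over
#' genes).
#'
#' @param ref,tgt gene-by-sample matrices on a common gene space.
#' @param k neighbourhood size (must be smaller than both batch sizes).
#' @return data.frame with integer columns `ref` and `tgt`.
#' @export
find_mnn_pairs <- function(ref, tgt, k) {
  nr <- ncol(ref); nt <- ncol(tgt)
  if (k >= nr || k >= nt) stop("k must be smaller than both batch sizes")
  # squared cross-distances
  d2 <- outer(colSums(ref^2), rep(1, nt)) + outer(rep(1, nr), colSums(tgt^2)) -
    2 * crossprod(ref, tgt)                        # nr x nt
  near_ref <- apply(d2, 2, function(col) order(col)[seq_len(k)])  # k x nt
  near_tgt <- apply(d2, 1, function(row) order(row)[seq_len(k)])  # k x nr
  pairs <- list()
  for (t in seq_len(nt)) {
    for (r in near_ref[, t]) {
      if (t %in% near_tgt[, r]) pairs[[length(pairs) + 1L]] <- c(r, t)
    }
  }
  if (!length(pairs))
    return(data.frame(ref = integer(0), tgt = integer(0)))
  m <- do.call(rbind, pairs)
  data.frame(ref = m[, 1], tgt = m[, 2])
}

#' Mutual-nearest-neighbour batch correction
#'
#' Batches are merged sequentially in batch-label order. For each new batch,
#' MNN pairs against the growing reference define per-pair correction vectors
#' (reference minus target, original scale); each target sample receives a
#' Gaussian-kernel-weighted average of these vectors, with kernel distances
#' and pair finding computed on cosine-normalized data (bandwidth `sigma`).
#' Each pair's weight combines its distance to the sample with the pair's own
#' span, so tight pairs dominate loose ones: a batch that is an exact shifted
#' copy of the reference is corrected essentially exactly through its
#' self-pairs.
#'
#' @inheritParams correct_limma
#' @param k neighbourhood size; capped at the smallest batch size minus one.
#' @param sigma Gaussian smoothing bandwidth on the cosine-normalized scale.
#' @param cosine cosine-normalize samples for pair finding (recommended).
#' @return a `correction_result`.
#' @export
correct_mnn <- function(meta, k = 20, sigma = 0.1, cosine = TRUE) {
  p <- meta_parts(meta)
  mat <- p$matrix
  batch <- p$batch
  levels_b <- sort(unique(batch))
  if (length(levels_b) < 2) {
    return(correction_result("mnnCorrect", mat, meta,
                             list(k = k, sigma = sigma)))
  }
  min_batch <- min(table(batch))
  if (k >= min_batch) k <- min_batch - 1L
  if (k < 1) stop("k must be >= 1 and smaller than every batch size")

  normalize <- function(m) {
    nrm <- sqrt(colSums(m^2))
    nrm[nrm == 0] <- 1
    sweep(m, 2, nrm, "/")
  }

  out <- mat
  normed <- if (cosine) normalize(mat) else mat
  ref_idx <- which(batch == levels_b[1])
  for (b in levels_b[-1]) {
    tgt_idx <- which(batch == b)
    pairs <- find_mnn_pairs(normed[, ref_idx, drop = FALSE],
                            normed[, tgt_idx, drop = FALSE], k)
    if (!nrow(pairs)) stop("no MNN pairs found for batch ", b)
    # correction vectors on the original scale
    V <- out[, ref_idx[pairs$ref], drop = FALSE] -
      out[, tgt_idx[pairs$tgt], drop = FALSE]            # G x P
    pair_loc <- normed[, tgt_idx[pairs$tgt], drop = FALSE]
    # squared span of each pair (penalizes wide, less reliable pairs)
    d2_span <- colSums((normed[, ref_idx[pairs$ref], drop = FALSE] - pair_loc)^2)
    for (s in seq_along(tgt_idx)) {
      d2 <- colSums((pair_loc - normed[, tgt_idx[s]])^2) + d2_span
      w <- exp(-d2 / (2 * sigma^2))
      if (sum(w) < 1e-300) w <- as.numeric(d2 == min(d2))
      out[, tgt_idx[s]] <- out[, tgt_idx[s]] + drop(V %*% (w / sum(w)))
    }
    normed[, tgt_idx] <- if (cosine) normalize(out[, tgt_idx, drop = FALSE])
                         else out[, tgt_idx, drop = FALSE]
    ref_idx <- c(ref_idx, tgt_idx)
  }
  correction_result("mnnCorrect", out, meta,
                    list(k = k, sigma = sigma, cosine = cosine))
}
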
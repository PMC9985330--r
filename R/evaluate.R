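# Score a set of correction results against the meta-experiment.

# Matrix on the metric (log) analysis scale for one correction result.
analysis_matrix <- function(res) {
  if (res$scale == "counts") log_transform_counts(res$matrix) else res$matrix
}

#' Score correction results with the six evaluation metrics
#'
#' Each corrected matrix (count-scale results are log-CPM transformed first)
#' is embedded by PCA and scored with PVCA batch/biology proportions (e1,
#' e4), the absolute mean batch silhouette (e2), eigenvalue-weighted PC
#' regression on batch (e3), normalized batch-mixing entropy (e5), and the
#' conserved highly-variable-gene ratio against the union of per-experiment
#' HVG sets (e6). The entropy draw uses one seed for all methods so scores
#' are comparable and deterministic.
#'
#' @param meta the source `meta_experiment`.
#' @param results list of `correction_result` objects (typically including an
#'   identity "uncorrected" entry).
#' @param n_pcs PCA components for embedding-based metrics (default 20).
#' @param entropy_n,entropy_k query count and neighbourhood size for the
#'   entropy metric.
#' @param hvg_n HVG count per call (default as in [detect_hvg()]).
#' @param pvca_threshold cumulative-variance cutoff for PVCA PC retention.
#' @param seed seed for the entropy query draw.
#' @return data.frame with columns `method`, `e1`..`e6`.
#' @export
evaluate_corrections <- function(meta, results, n_pcs = 20, entropy_n = 100,
                                 entropy_k = 15, hvg_n = NULL,
                                 pvca_threshold = 0.6, seed = 1) {
  p <- meta_parts(meta)
  base_mat <- if (identical(meta$technology, "rnaseq"))
    log_transform_counts(p$matrix) else p$matrix
  exp_mats <- split_by_batch(base_mat, p$batch)

  rows <- lapply(results, function(res) {
    mat <- analysis_matrix(res)
    emb <- pca_embed(mat, n_pcs)
    pv <- eval_pvca(mat, p$batch, p$bio, threshold = pvca_threshold,
                    n_components = n_pcs)
    data.frame(
      method = res$method,
      e1 = pv$e1,
      e2 = eval_silhouette(emb, p$batch),
      e3 = eval_pcregression(emb, p$batch),
      e4 = pv$e4,
      e5 = eval_entropy(emb, p$batch, n_queries = entropy_n,
                        k_neighbours = entropy_k, seed = seed),
      e6 = eval_hvg_union(mat, exp_mats, n_top = hvg_n),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Identity ("uncorrected") baseline result
#'
#' Wraps the meta-experiment's own matrix as a correction result so the
#' uncorrected data participate in evaluation and ranking. For RNA-seq the
#' matrix stays on the count scale (it is log-CPM transformed at evaluation
#' time).
#'
#' @param meta a `meta_experiment`.
#' @return a `correction_result` labelled "uncorrected".
#' @export
uncorrected_result <- function(meta) {
  correction_result("uncorrected", meta$matrix, meta, list(),
                    scale = if (identical(meta$technology, "rnaseq"))
                      "counts" else "log")
}
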
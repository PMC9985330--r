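# Rank aggregation: transform raw metric scores so that rank 1 always means
# "best", dense-rank each metric, and dense-rank the rank sums (sumRank).

#' Dense descending rank
#'
#' Largest value gets rank 1, ties share a rank, and ranks over distinct
#' values are consecutive (no gaps).
#'
#' @param values finite numeric vector.
#' @return integer vector of ranks.
#' @export
dense_rank_desc <- function(values) {
  if (any(!is.finite(values))) stop("non-finite values")
  u <- sort(unique(values), decreasing = TRUE)
  match(values, u)
}

#' Per-metric dense ranks of an evaluation matrix
#'
#' The batch-effect metrics e1-e3 are negated before ranking (so the smallest
#' raw batch-effect score gets rank 1); the biology-preservation metrics
#' e4-e6 are ranked directly (largest raw score gets rank 1).
#'
#' @param evaluation data.frame with a `method` column and columns `e1`..`e6`
#'   (see [evaluate_corrections()]).
#' @return data.frame of per-metric dense ranks with the same `method` column.
#' @export
transform_and_rank <- function(evaluation) {
  metrics <- paste0("e", 1:6)
  stopifnot(all(c("method", metrics) %in% colnames(evaluation)))
  if (anyDuplicated(evaluation$method)) stop("method labels must be unique")
  ranks <- data.frame(method = evaluation$method, stringsAsFactors = FALSE)
  for (mcol in metrics) {
    x <- evaluation[[mcol]]
    bad <- which(!is.finite(x))
    if (length(bad))
      stop("non-finite score for method '", evaluation$method[bad[1]],
           "', metric ", mcol)
    ranks[[mcol]] <- if (mcol %in% c("e1", "e2", "e3")) dense_rank_desc(-x)
                     else dense_rank_desc(x)
  }
  ranks
}

#' Aggregate per-metric ranks into the final sumRank
#'
#' `rank_sum` is the sum of the six per-metric ranks; `sumRank` is its dense
#' ascending rank (smallest sum gets sumRank 1, ties share a rank). The
#' returned table is ordered by sumRank, then alphabetically by method.
#'
#' @param ranks output of [transform_and_rank()].
#' @return data.frame with per-metric ranks, `rank_sum` and `sumRank`.
#' @export
sum_rank <- function(ranks) {
  metrics <- paste0("e", 1:6)
  stopifnot(all(c("method", metrics) %in% colnames(ranks)))
  out <- ranks
  out$rank_sum <- rowSums(out[, metrics])
  u <- sort(unique(out$rank_sum))
  out$sumRank <- match(out$rank_sum, u)
  out[order(out$sumRank, out$method), , drop = FALSE]
}

#' Write the diagnostic report
#'
#' Writes `evaluation_matrix.tsv` (raw scores), `rank_table.tsv` (per-metric
#' ranks, rank sum, sumRank; sorted so the first row is the sumRank-1
#' method), a heatmap of the per-metric ranks (`rank_heatmap.png`) and a bar
#' chart of sumRank (`sumrank_barplot.png`). Content is deterministic given
#' the inputs.
#'
#' @param evaluation raw evaluation matrix (data.frame, see
#'   [evaluate_corrections()]).
#' @param ranks output of [sum_rank()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, the paths of the four files written.
#' @export
diagnostic_report <- function(evaluation, ranks, out_dir) {
  if (!nrow(evaluation)) stop("empty method list")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  ranks <- sum_rank(ranks[, c("method", paste0("e", 1:6))])

  f1 <- file.path(out_dir, "evaluation_matrix.tsv")
  utils::write.table(evaluation, f1, sep = "\t", quote = FALSE, row.names = FALSE)
  f2 <- file.path(out_dir, "rank_table.tsv")
  utils::write.table(ranks, f2, sep = "\t", quote = FALSE, row.names = FALSE)

  metrics <- paste0("e", 1:6)
  labels <- c("PVCA:batch", "silhouette", "pcRegression",
              "PVCA:bio", "entropy", "HVG.union")
  rk <- as.matrix(ranks[, metrics])
  rownames(rk) <- ranks$method

  f3 <- file.path(out_dir, "rank_heatmap.png")
  grDevices::png(f3, width = 720, height = 160 + 40 * nrow(rk))
  op <- graphics::par(mar = c(6, 10, 3, 2))
  pal <- grDevices::hcl.colors(max(rk), "Blues 3", rev = TRUE)
  graphics::image(seq_len(ncol(rk)), seq_len(nrow(rk)), t(rk[rev(seq_len(nrow(rk))), ]),
                  col = pal, axes = FALSE, xlab = "", ylab = "",
                  main = "Per-metric dense ranks (1 = best)")
  graphics::axis(1, at = seq_len(ncol(rk)), labels = labels, las = 2)
  graphics::axis(2, at = seq_len(nrow(rk)), labels = rev(rownames(rk)), las = 1)
  for (i in seq_len(nrow(rk))) for (j in seq_len(ncol(rk)))
    graphics::text(j, nrow(rk) - i + 1, rk[i, j], cex = 0.9)
  graphics::par(op)
  grDevices::dev.off()

  f4 <- file.path(out_dir, "sumrank_barplot.png")
  grDevices::png(f4, width = 720, height = 480)
  op <- graphics::par(mar = c(9, 4, 3, 1))
  graphics::barplot(ranks$sumRank, names.arg = ranks$method, las = 2,
                    ylab = "sumRank (1 = recommended)",
                    main = "Final prioritization of batch-correction methods",
                    col = "steelblue")
  graphics::par(op)
  grDevices::dev.off()

  invisible(c(f1, f2, f3, f4))
}
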
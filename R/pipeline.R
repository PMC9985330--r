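# End-to-end pipeline: link -> merge -> correct -> evaluate -> rank -> report.

microarray_methods <- c("limma", "ComBat1", "ComBat2", "Q_ComBat",
                        "naiveRandRUV_HK", "naiveRandRUV_empi.controls",
                        "Q_naiveRandRUV_HK", "Q_naiveRandRUV_empi.controls",
                        "mnnCorrect")
count_methods <- c("ComBatseq_null", "ComBatseq_full", "RUVs")

#' Batch-correction methods applicable to a technology
#'
#' @param technology `"microarray"` or `"rnaseq"`.
#' @return character vector of method labels (excluding "uncorrected", which
#'   is always evaluated).
#' @export
available_methods <- function(technology = c("microarray", "rnaseq")) {
  technology <- match.arg(technology)
  if (technology == "rnaseq") c(microarray_methods, count_methods)
  else microarray_methods
}

# Dispatch one method. `logmeta` carries the log-scale matrix (identical to
# `meta` for microarray); count-native methods get the raw count meta.
run_method <- function(method, meta, logmeta) {
  switch(method,
    "limma" = correct_limma(logmeta),
    "ComBat1" = correct_combat(logmeta, mode = "parametric"),
    "ComBat2" = correct_combat(logmeta, mode = "nonparametric"),
    "Q_ComBat" = correct_q_combat(logmeta),
    "naiveRandRUV_HK" = correct_naive_ruv(logmeta, controls = "housekeeping"),
    "naiveRandRUV_empi.controls" = correct_naive_ruv(logmeta, controls = "empirical"),
    "Q_naiveRandRUV_HK" = correct_naive_ruv(logmeta, controls = "housekeeping",
                                            pre_quantile = TRUE),
    "Q_naiveRandRUV_empi.controls" = correct_naive_ruv(logmeta, controls = "empirical",
                                                       pre_quantile = TRUE),
    "mnnCorrect" = correct_mnn(logmeta),
    "ComBatseq_null" = correct_combatseq(meta, model = "null"),
    "ComBatseq_full" = correct_combatseq(meta, model = "full"),
    "RUVs" = correct_ruvs(meta),
    stop("unknown method: ", method)
  )
}

#' Run the full benchmarking pipeline
#'
#' Links the input experiments through the biological covariate, filters
#' unlinked ones, merges the retained set into a meta-experiment, applies
#' every requested batch-correction method (always evaluating the
#' uncorrected baseline too), scores each result with the six metrics, and
#' aggregates the scores into the final sumRank prioritization. For RNA-seq,
#' Gaussian methods operate on log-CPM while count-native methods receive the
#' raw counts; all metrics are computed on the log scale. Outputs
#' (evaluation matrix, rank table, plots, per-method corrected matrices,
#' `run.log`) are written to `out_dir` only after all stages succeed, so a
#' failed run leaves no partial outputs.
#'
#' @param experiments list of [experiment()] objects, or a data.frame with
#'   columns `id`, `matrix`, `meta` naming TSV files to read.
#' @param bio_covariate metadata column used for linking and as the
#'   biological factor of the evaluation.
#' @param out_dir output directory; `NULL` skips writing.
#' @param technology `"microarray"` or `"rnaseq"`; default taken from the
#'   experiments.
#' @param methods method labels (see [available_methods()]); default all
#'   applicable. Housekeeping RUV variants are dropped (with a log entry)
#'   when no packaged housekeeping gene is present in the meta-experiment.
#' @param seed top-level seed; all stage randomness derives from it.
#' @param n_pcs,entropy_n,entropy_k,hvg_n,pvca_threshold metric parameters,
#'   see [evaluate_corrections()].
#' @param external named list of externally corrected matrices (or TSV
#'   paths), e.g. from a method not implemented here; each is injected into
#'   evaluation and ranking without a correction stage. Matrices must match
#'   the meta-experiment's genes and samples and be on the log analysis
#'   scale.
#' @return object of class `bcm_benchmark`: the meta-experiment, correction
#'   results, raw `evaluation` matrix, `ranks` table and the run log.
#' @export
run_pipeline <- function(experiments, bio_covariate, out_dir = NULL,
                         technology = NULL, methods = NULL, seed = 1,
                         n_pcs = 20, entropy_n = 100, entropy_k = 15,
                         hvg_n = NULL, pvca_threshold = 0.6, external = NULL) {
  log <- new_log()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage [", name, "]: ", conditionMessage(e), call. = FALSE))
  }

  if (is.data.frame(experiments)) {
    stopifnot(all(c("id", "matrix", "meta") %in% colnames(experiments)))
    tech <- technology %||% "microarray"
    experiments <- stage("read", Map(function(id, m, s)
      read_experiment(m, s, technology = tech, id = id, log = log),
      experiments$id, experiments$matrix, experiments$meta))
  }
  if (length(experiments) < 2) stop("need >= 2 experiment inputs")
  technology <- technology %||% experiments[[1]]$technology

  methods <- methods %||% available_methods(technology)
  bad <- setdiff(methods, available_methods(technology))
  if (length(bad))
    stop("method(s) not applicable to ", technology, ": ",
         paste(bad, collapse = ", "))

  linked <- stage("link", link_experiments(experiments, bio_covariate, log = log))
  meta <- stage("merge", merge_experiments(linked$retained, bio_covariate, log = log))

  logmeta <- meta
  if (identical(technology, "rnaseq")) {
    logmeta$matrix <- stage("log_transform", log_transform_counts(meta))
    log_line(log, "rnaseq input: Gaussian methods receive log2(CPM + 1)")
  }

  hk_overlap <- length(intersect(housekeeping_genes(), rownames(meta$matrix)))
  if (hk_overlap == 0) {
    hk_methods <- intersect(methods, c("naiveRandRUV_HK", "Q_naiveRandRUV_HK"))
    if (length(hk_methods)) {
      log_line(log, "no housekeeping genes in the meta-experiment; dropping: ",
               paste(hk_methods, collapse = ", "))
      methods <- setdiff(methods, hk_methods)
    }
  }

  results <- list(uncorrected = uncorrected_result(meta))
  for (m in methods) {
    results[[m]] <- stage(paste0("correct:", m),
                          suppressWarnings(run_method(m, meta, logmeta)))
    log_line(log, "corrected with ", m)
  }
  if (!is.null(external)) {
    for (lab in names(external)) {
      x <- external[[lab]]
      if (is.character(x)) x <- read_tsv_matrix(x)
      x <- x[rownames(meta$matrix), colnames(meta$matrix), drop = FALSE]
      results[[lab]] <- stage(paste0("external:", lab),
                              correction_result(lab, x, meta, list(external = TRUE)))
      log_line(log, "injected external corrected matrix: ", lab)
    }
  }

  entropy_seed <- substream(seed, 7)
  evaluation <- stage("evaluate",
    evaluate_corrections(meta, results, n_pcs = n_pcs, entropy_n = entropy_n,
                         entropy_k = entropy_k, hvg_n = hvg_n,
                         pvca_threshold = pvca_threshold, seed = entropy_seed))
  ranks <- stage("rank", sum_rank(transform_and_rank(evaluation)))
  log_line(log, "top-ranked method: ", ranks$method[1],
           " (sumRank ", ranks$sumRank[1], ")")

  if (!is.null(out_dir)) {
    stage("report", {
      diagnostic_report(evaluation, ranks, out_dir)
      cor_dir <- file.path(out_dir, "corrected")
      dir.create(cor_dir, recursive = TRUE, showWarnings = FALSE)
      for (res in results)
        write_tsv_matrix(res$matrix, file.path(cor_dir, paste0(res$method, ".tsv")))
      writeLines(log$lines, file.path(out_dir, "run.log"))
    })
  }

  structure(
    list(meta = meta, results = results, evaluation = evaluation,
         ranks = ranks, seed = seed, out_dir = out_dir, log = log$lines),
    class = "bcm_benchmark"
  )
}

#' @export
print.bcm_benchmark <- function(x, ...) {
  cat("<bcm_benchmark> ", nrow(x$meta$matrix), " genes x ",
      ncol(x$meta$matrix), " samples, ", length(unique(x$meta$batch)),
      " batches (", x$meta$technology, ")\n", sep = "")
  top <- x$ranks[x$ranks$sumRank == 1, "method"]
  cat("  methods evaluated: ", nrow(x$ranks), "\n", sep = "")
  cat("  recommended: ", paste(top, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.bcm_benchmark <- function(object, ...) {
  cat("Evaluation matrix (raw metric scores):\n")
  ev <- object$evaluation
  ev[, -1] <- round(ev[, -1], 4)
  print(ev, row.names = FALSE)
  cat("\nRank table (1 = best; sumRank 1 = recommended):\n")
  print(object$ranks, row.names = FALSE)
  invisible(object)
}

#' @export
plot.bcm_benchmark <- function(x, ...) {
  op <- graphics::par(mar = c(9, 4, 3, 1))
  on.exit(graphics::par(op))
  graphics::barplot(x$ranks$sumRank, names.arg = x$ranks$method, las = 2,
                    ylab = "sumRank (1 = recommended)",
                    main = "Batch-correction method prioritization",
                    col = "steelblue", ...)
  invisible(x)
}
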
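# Synthetic meta-experiment generator with known ground truth. The
# microarray model mirrors the location/scale assumptions of the
# empirical-Bayes correction (per-batch per-gene additive offsets and
# multiplicative noise-scale factors on log intensities); the count model
# mirrors the negative-binomial batch model (per-batch mean fold-changes and
# dispersion multipliers).

#' Simulation configuration
#'
#' Defaults emulate a small multi-study bulk meta-experiment: log-intensity
#' baselines around 7 +/- 1.5 (typical log2 microarray range), a 1-unit
#' biological effect on 10% of genes, batch location offsets with s.d. 1 and
#' noise-scale factors with log-s.d. 0.3 on every gene (the location/scale
#' model), measurement noise s.d. 0.5; for counts, log-normal base means, a
#' 2-fold batch mean shift on the affected fraction and a 1.5x dispersion
#' multiplier in non-reference batches.
#'
#' @param n_genes number of genes.
#' @param batches named integer vector of per-batch sample counts.
#' @param bio_levels category labels of the biological covariate; samples are
#'   assigned round-robin within each batch.
#' @param bio_effect additive effect (log scale) or log2 fold-change (counts)
#'   for non-reference biology levels.
#' @param bio_frac fraction of genes carrying the biological effect.
#' @param batch_sd s.d. of the per-batch per-gene location offsets (log scale).
#' @param scale_sd log-s.d. of the per-batch per-gene noise-scale factors.
#' @param affected_frac fraction of genes affected by batch.
#' @param noise_sd measurement noise s.d. (log scale).
#' @param batch_lfc per-batch log2 fold-change of counts on affected genes
#'   (non-reference batches).
#' @param disp_mult dispersion multiplier of non-reference batches (counts).
#' @param base_meanlog,base_sdlog log-normal parameters of count base means.
#' @param dispersion baseline NB dispersion (1/size).
#' @param seed mandatory RNG seed.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1000,
                       batches = c(b1 = 10, b2 = 10, b3 = 10),
                       bio_levels = c("ctrl", "case"),
                       bio_effect = 1, bio_frac = 0.1,
                       batch_sd = 1, scale_sd = 0.3, affected_frac = 1,
                       noise_sd = 0.5,
                       batch_lfc = 1, disp_mult = 1.5,
                       base_meanlog = 4, base_sdlog = 1.2, dispersion = 0.15,
                       seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (n_genes < 1 || any(batches < 1)) stop("counts must be positive")
  if (length(batches) < 2) stop("need >= 2 batches")
  if (is.null(names(batches)) || anyDuplicated(names(batches)))
    stop("batches must have unique names")
  for (f in c(bio_frac, affected_frac))
    if (f < 0 || f > 1) stop("fractions must lie in [0, 1]")
  if (length(bio_levels) < 1) stop("need >= 1 biology level")
  structure(as.list(environment()), class = "sim_config")
}

sim_assignments <- function(config) {
  batch <- rep(names(config$batches), config$batches)
  bio <- unlist(lapply(config$batches, function(n)
    rep_len(config$bio_levels, n)), use.names = FALSE)
  samples <- unlist(lapply(names(config$batches), function(b)
    paste0(b, "_s", seq_len(config$batches[[b]]))), use.names = FALSE)
  list(batch = batch, bio = bio, samples = samples)
}

sim_to_experiments <- function(mat, asg, config, technology) {
  lapply(names(config$batches), function(b) {
    idx <- which(asg$batch == b)
    meta <- data.frame(condition = asg$bio[idx], row.names = asg$samples[idx],
                       stringsAsFactors = FALSE)
    experiment(mat[, idx, drop = FALSE], meta, technology = technology, id = b)
  })
}

#' Simulate a microarray-style meta-experiment
#'
#' Generative model per gene g, batch b, sample j:
#' `Y = mu_g + bio_effect * 1[affected bio gene] + gamma_gb + delta_gb * eps`,
#' with `mu_g ~ N(7, 1.5^2)`, `gamma_gb ~ N(0, batch_sd^2)` and
#' `delta_gb ~ LogNormal(0, scale_sd^2)` on the batch-affected genes,
#' `eps ~ N(0, noise_sd^2)`. The ground truth stores the exact batch-free
#' matrix (`signal + eps`) plus the batch components.
#'
#' @param config a [sim_config()].
#' @return list with `experiments` (one [experiment()] per batch) and `truth`
#'   (`clean` batch-free matrix, `signal`, `gamma`, `delta`, the affected
#'   gene indices, and per-sample `batch`/`bio`).
#' @export
simulate_microarray_meta <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  asg <- sim_assignments(config)
  G <- config$n_genes; S <- length(asg$batch)
  B <- length(config$batches)
  genes <- sprintf("gene%05d", seq_len(G))

  with_seed(config$seed, {
    mu <- stats::rnorm(G, 7, 1.5)
    bio_genes <- sample.int(G, round(config$bio_frac * G))
    affected <- sample.int(G, round(config$affected_frac * G))
    gamma <- matrix(0, G, B, dimnames = list(genes, names(config$batches)))
    delta <- matrix(1, G, B, dimnames = list(genes, names(config$batches)))
    if (length(affected)) {
      gamma[affected, ] <- stats::rnorm(length(affected) * B, 0, config$batch_sd)
      delta[affected, ] <- exp(stats::rnorm(length(affected) * B, 0, config$scale_sd))
    }
    signal <- matrix(mu, G, S)
    if (length(bio_genes) && length(config$bio_levels) > 1) {
      for (l in seq_along(config$bio_levels)[-1]) {
        cols <- which(asg$bio == config$bio_levels[l])
        signal[bio_genes, cols] <- signal[bio_genes, cols] +
          config$bio_effect * (l - 1)
      }
    }
    eps <- matrix(stats::rnorm(G * S, 0, config$noise_sd), G, S)
    bidx <- match(asg$batch, names(config$batches))
    obs <- signal + gamma[, bidx] + delta[, bidx] * eps
    clean <- signal + eps
    dimnames(obs) <- dimnames(clean) <- dimnames(signal) <- list(genes, asg$samples)

    truth <- list(clean = clean, signal = signal, gamma = gamma, delta = delta,
                  bio_genes = genes[bio_genes], affected = genes[affected],
                  batch = stats::setNames(asg$batch, asg$samples),
                  bio = stats::setNames(asg$bio, asg$samples), config = config)
    list(experiments = sim_to_experiments(obs, asg, config, "microarray"),
         truth = truth)
  })
}

#' Simulate an RNA-seq count meta-experiment
#'
#' Counts are drawn from a negative binomial with log-normal gene base means;
#' on batch-affected genes, non-reference batches multiply the mean by
#' `2^batch_lfc` and the dispersion by `disp_mult`. Biology-affected genes
#' carry a `2^(bio_effect * level_index)` fold-change. The ground truth
#' stores the batch-free NB means and dispersions.
#'
#' @inheritParams simulate_microarray_meta
#' @return list with `experiments` and `truth` (`mu_free`, `size_free`,
#'   affected gene ids, batch/bio assignments).
#' @export
simulate_count_meta <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  asg <- sim_assignments(config)
  G <- config$n_genes; S <- length(asg$batch)
  B <- length(config$batches)
  genes <- sprintf("gene%05d", seq_len(G))

  with_seed(config$seed, {
    base <- stats::rlnorm(G, config$base_meanlog, config$base_sdlog)
    bio_genes <- sample.int(G, round(config$bio_frac * G))
    affected <- sample.int(G, round(config$affected_frac * G))

    bio_mult <- matrix(1, G, S)
    if (length(bio_genes) && length(config$bio_levels) > 1) {
      for (l in seq_along(config$bio_levels)[-1]) {
        cols <- which(asg$bio == config$bio_levels[l])
        bio_mult[bio_genes, cols] <- 2^(config$bio_effect * (l - 1))
      }
    }
    mu_free <- base * bio_mult
    phi_free <- rep(config$dispersion, G)

    batch_mult <- matrix(1, G, S)
    phi <- matrix(phi_free, G, S)
    ref <- names(config$batches)[1]
    nonref_cols <- which(asg$batch != ref)
    if (length(affected) && length(nonref_cols)) {
      batch_mult[affected, nonref_cols] <- 2^config$batch_lfc
      phi[affected, nonref_cols] <- phi[affected, nonref_cols] * config$disp_mult
    }
    mu <- mu_free * batch_mult
    counts <- matrix(stats::rnbinom(G * S, mu = mu, size = 1 / phi), G, S)
    dimnames(counts) <- dimnames(mu_free) <- list(genes, asg$samples)

    truth <- list(mu_free = mu_free, size_free = 1 / phi_free,
                  bio_genes = genes[bio_genes], affected = genes[affected],
                  batch = stats::setNames(asg$batch, asg$samples),
                  bio = stats::setNames(asg$bio, asg$samples), config = config)
    list(experiments = sim_to_experiments(counts, asg, config, "rnaseq"),
         truth = truth)
  })
}

#' Oracle correction of a simulated microarray meta-experiment
#'
#' Removes the exact simulated batch components:
#' `(observed - signal - gamma)/delta + signal`, recovering the batch-free
#' matrix `signal + eps` exactly. Used as the ground-truth reference when
#' checking that the metrics discriminate batch effect.
#'
#' @param meta merged `meta_experiment` built from the simulated experiments.
#' @param truth the `truth` element of [simulate_microarray_meta()].
#' @return corrected matrix aligned to `meta$matrix`.
#' @export
oracle_correct <- function(meta, truth) {
  mat <- meta$matrix
  genes <- rownames(mat)
  samples <- colnames(mat)
  bidx <- match(truth$batch[samples], colnames(truth$gamma))
  sig <- truth$signal[genes, samples, drop = FALSE]
  gam <- truth$gamma[genes, , drop = FALSE][, bidx, drop = FALSE]
  del <- truth$delta[genes, , drop = FALSE][, bidx, drop = FALSE]
  (mat - sig - gam) / del + sig
}

#' Write simulated experiments as TSV pairs
#'
#' One `<id>_matrix.tsv` / `<id>_samples.tsv` pair per experiment, plus
#' `ground_truth/` (batch-free matrix for microarray, batch-free means for
#' counts) and `sim_config.json`.
#'
#' @param sim result of [simulate_microarray_meta()] or
#'   [simulate_count_meta()].
#' @param out_dir output directory.
#' @return invisibly, `out_dir`.
#' @export
write_simulation <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (e in sim$experiments) {
    write_tsv_matrix(e$matrix, file.path(out_dir, paste0(e$id, "_matrix.tsv")))
    meta <- data.frame(sample_id = colnames(e$matrix), e$sample_meta,
                       stringsAsFactors = FALSE)
    utils::write.table(meta, file.path(out_dir, paste0(e$id, "_samples.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  gt_dir <- file.path(out_dir, "ground_truth")
  dir.create(gt_dir, showWarnings = FALSE)
  if (!is.null(sim$truth$clean))
    write_tsv_matrix(sim$truth$clean, file.path(gt_dir, "batch_free_matrix.tsv"))
  if (!is.null(sim$truth$mu_free))
    write_tsv_matrix(sim$truth$mu_free, file.path(gt_dir, "batch_free_means.tsv"))
  cfg <- sim$truth$config
  cfg_list <- unclass(cfg)
  cfg_list$batches <- as.list(cfg_list$batches)
  jsonlite::write_json(cfg_list, file.path(out_dir, "sim_config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
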
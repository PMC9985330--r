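# In-code fixtures shared across test files.

# Plain-list meta input (matrix/batch/bio) for correction-level tests that
# exercise edge cases outside the strict meta_experiment invariants.
rand_meta <- function(n_genes, batch_sizes, n_bio = 2, seed = 1,
                      batch_shift = 0, sd = 1) {
  set.seed(seed)
  batch <- rep(paste0("b", seq_along(batch_sizes)), batch_sizes)
  S <- length(batch)
  mat <- matrix(rnorm(n_genes * S, mean = 5, sd = sd), n_genes, S,
                dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                                sprintf("s%03d", seq_len(S))))
  if (batch_shift != 0) {
    for (i in seq_along(batch_sizes)[-1]) {
      idx <- which(batch == paste0("b", i))
      mat[, idx] <- mat[, idx] + batch_shift * (i - 1)
    }
  }
  bio <- rep_len(paste0("c", seq_len(n_bio)), S)
  list(matrix = mat, batch = batch, bio = bio)
}

# Merge the experiments of a simulation into a meta_experiment.
sim_meta <- function(sim) merge_experiments(sim$experiments, "condition")

# Tiny experiment built in code.
mini_experiment <- function(id, genes, samples, values, bio,
                            technology = "microarray") {
  mat <- matrix(values, length(genes), length(samples),
                dimnames = list(genes, samples))
  meta <- data.frame(disease = bio, row.names = samples,
                     stringsAsFactors = FALSE)
  experiment(mat, meta, technology = technology, id = id)
}

# Write an experiment to a matrix/metadata TSV pair; returns the two paths.
write_experiment_tsv <- function(mat, meta_df, dir = NULL) {
  if (is.null(dir)) {
    dir <- tempfile("fixture")
    dir.create(dir)
  }
  mp <- file.path(dir, "matrix.tsv")
  sp <- file.path(dir, "samples.tsv")
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  write.table(df, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(meta_df, sp, sep = "\t", quote = FALSE, row.names = FALSE)
  c(matrix = mp, meta = sp)
}
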
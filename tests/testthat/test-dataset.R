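test_that("read_experiment parses TSV pairs, drops incomplete genes, validates counts", {
  mat <- matrix(c(1.5, 2, 3, 4, 5, 6), 3, 2,
                dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  meta <- data.frame(sample_id = c("s1", "s2"), disease = c("RA", "ctrl"))
  paths <- write_experiment_tsv(mat, meta)
  e <- read_experiment(paths["matrix"], paths["meta"], "microarray", id = "A")
  expect_s3_class(e, "experiment")
  expect_equal(dim(e$matrix), c(3L, 2L))
  expect_equal(e$sample_meta["s2", "disease"], "ctrl")

  # a gene row with a missing cell is dropped
  mat_na <- mat; mat_na["g2", 1] <- NA
  paths <- write_experiment_tsv(mat_na, meta)
  e2 <- read_experiment(paths["matrix"], paths["meta"], "microarray")
  expect_equal(nrow(e2$matrix), 2L)
  expect_false("g2" %in% rownames(e2$matrix))

  # rnaseq requires non-negative integers
  mat_neg <- mat; mat_neg[1, 1] <- -1
  paths <- write_experiment_tsv(mat_neg, meta)
  expect_error(read_experiment(paths["matrix"], paths["meta"], "rnaseq"),
               "negative count")

  # duplicate gene ids are reported by name
  mat_dup <- rbind(mat, mat[1, , drop = FALSE])
  paths <- write_experiment_tsv(mat_dup, meta)
  expect_error(read_experiment(paths["matrix"], paths["meta"], "microarray"),
               "g1")

  # a matrix sample missing from the metadata is an error
  meta_short <- meta[1, , drop = FALSE]
  paths <- write_experiment_tsv(mat, meta_short)
  expect_error(read_experiment(paths["matrix"], paths["meta"], "microarray"),
               "s2")
})

test_that("linking retains the largest component and filters unlinked studies", {
  A <- mini_experiment("A", c("g1", "g2"), c("a1", "a2"), 1:4, c("RA", "ctrl"))
  B <- mini_experiment("B", c("g1", "g2"), c("b1", "b2"), 1:4, c("RA", "RA"))
  C <- mini_experiment("C", c("g1", "g2"), c("c1", "c2"), 1:4, c("OA", "OA"))
  link <- link_experiments(list(A, B, C), "disease")
  expect_setequal(names(link$retained), c("A", "B"))
  expect_equal(link$discarded$id, "C")

  # no shared category anywhere -> error
  B2 <- mini_experiment("B", c("g1", "g2"), c("b1", "b2"), 1:4, c("OA", "OA"))
  expect_error(link_experiments(list(A, B2), "disease"), "no linkable")

  # two components: {A,B} with 4+4 samples beats {C,D} with 3+3
  mk <- function(id, n, cat) mini_experiment(id, c("g1", "g2"),
                                             paste0(id, seq_len(n)),
                                             seq_len(2 * n), rep(cat, n))
  res <- link_experiments(list(mk("A", 4, "x"), mk("B", 4, "x"),
                               mk("C", 3, "y"), mk("D", 3, "y")), "disease")
  expect_setequal(names(res$retained), c("A", "B"))
  expect_equal(sort(res$discarded$id), c("C", "D"))
})

test_that("merging intersects genes, concatenates samples, tracks loss", {
  A <- mini_experiment("A", c("g1", "g2", "g3"), c("a1", "a2"), 1:6, c("RA", "ctrl"))
  B <- mini_experiment("B", c("g2", "g3", "g4"), c("b1", "b2"), 1:6, c("RA", "ctrl"))
  meta <- merge_experiments(list(A, B), "disease")
  expect_equal(rownames(meta$matrix), c("g2", "g3"))
  expect_equal(ncol(meta$matrix), 4L)
  expect_equal(unname(meta$batch), c("A", "A", "B", "B"))
  expect_equal(meta$genes_lost_frac, 0.5)

  # identical gene sets: nothing lost
  B2 <- mini_experiment("B", c("g1", "g2", "g3"), c("b1", "b2"), 1:6, c("RA", "ctrl"))
  expect_equal(merge_experiments(list(A, B2), "disease")$genes_lost_frac, 0)

  # disjoint gene sets
  B3 <- mini_experiment("B", c("h1", "h2"), c("b1", "b2"), 1:4, c("RA", "ctrl"))
  expect_error(merge_experiments(list(A, B3), "disease"), "empty intersection")

  # mixed technologies
  B4 <- mini_experiment("B", c("g1", "g2"), c("b1", "b2"), c(1L, 2L, 3L, 4L),
                        c("RA", "ctrl"), technology = "rnaseq")
  expect_error(merge_experiments(list(A, B4), "disease"), "mixed technologies")
})

test_that("merge is invariant to experiment input order", {
  sim <- simulate_microarray_meta(sim_config(n_genes = 30,
                                             batches = c(A = 3, B = 3, C = 4),
                                             seed = 5))
  m1 <- merge_experiments(sim$experiments, "condition")
  m2 <- merge_experiments(rev(sim$experiments), "condition")
  expect_identical(m1$matrix, m2$matrix)
  expect_identical(m1$batch, m2$batch)
  expect_identical(m1$bio, m2$bio)
})

test_that("duplicate sample ids across experiments are disambiguated by prefix", {
  A <- mini_experiment("A", c("g1", "g2"), c("s1", "s2"), 1:4, c("RA", "ctrl"))
  B <- mini_experiment("B", c("g1", "g2"), c("s1", "s2"), 5:8, c("RA", "ctrl"))
  meta <- merge_experiments(list(A, B), "disease")
  expect_equal(colnames(meta$matrix), c("A.s1", "A.s2", "B.s1", "B.s2"))
})

test_that("meta-experiment bundles round-trip", {
  sim <- simulate_microarray_meta(sim_config(n_genes = 25,
                                             batches = c(A = 3, B = 3),
                                             seed = 9))
  meta <- sim_meta(sim)
  dir <- tempfile("bundle")
  write_meta(meta, dir)
  back <- read_meta(dir)
  expect_equal(back$matrix, meta$matrix, tolerance = 1e-12)
  expect_identical(unname(back$batch), unname(meta$batch))
  expect_identical(back$technology, meta$technology)

  # integer counts come back bit-exactly
  simc <- simulate_count_meta(sim_config(n_genes = 25, batches = c(A = 3, B = 3),
                                         seed = 9))
  metac <- sim_meta(simc)
  dir2 <- tempfile("bundle")
  write_meta(metac, dir2)
  expect_identical(read_meta(dir2)$matrix, metac$matrix)
})
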
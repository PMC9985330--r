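test_that("PCA embedding reproduces the covariance eigendecomposition", {
  # rank-1 matrix: one non-zero eigenvalue, proportion 1
  r1 <- outer(1:5, c(1, 2, 3, 4)) + 0
  dimnames(r1) <- list(paste0("g", 1:5), paste0("s", 1:4))
  emb <- pca_embed(r1)
  expect_equal(emb$proportion[1], 1)
  expect_lt(emb$eigenvalues[2] / emb$eigenvalues[1], 1e-12)

  set.seed(81)
  mat <- matrix(rnorm(100 * 30), 100, 30,
                dimnames = list(paste0("g", 1:100), paste0("s", 1:30)))
  emb <- pca_embed(mat, n_components = 20)
  # eigenvalues match a brute-force eigendecomposition of the sample covariance
  ev <- eigen(cov(scale(t(mat), center = TRUE, scale = FALSE)), symmetric = TRUE)$values
  expect_equal(emb$eigenvalues, ev[1:20], tolerance = 1e-8)
  # retained eigenvalue sum below total variance; equality with all components
  expect_lt(sum(emb$eigenvalues), emb$total_variance)
  emb_all <- pca_embed(mat, n_components = 29)
  expect_equal(sum(emb_all$eigenvalues), emb_all$total_variance, tolerance = 1e-10)

  expect_error(pca_embed(matrix(1, 5, 4)), "zero variance")
})

test_that("variance-component proportions are normalized and detect dominant batch", {
  sim_pvca <- function(seed, sd_batch, sd_bio, sd_noise) {
    set.seed(seed)
    batch <- rep(c("A", "B", "C"), each = 6)
    bio <- rep_len(c("x", "y"), 18)
    G <- 100
    mat <- matrix(rnorm(G * 18, 0, sd_noise), G, 18)
    mat <- mat + matrix(rnorm(G * 3, 0, sd_batch), G, 3)[, match(batch, c("A", "B", "C"))]
    mat <- mat + matrix(rnorm(G * 2, 0, sd_bio), G, 2)[, match(bio, c("x", "y"))]
    dimnames(mat) <- list(paste0("g", 1:G), paste0("s", 1:18))
    eval_pvca(mat, batch, bio)
  }

  pv <- sim_pvca(1, 2, 1, 1)
  expect_equal(sum(pv$proportions), 1, tolerance = 1e-6)
  expect_true(all(abs(rowSums(pv$per_pc) - 1) < 1e-6))

  # batch:bio:noise variance 8:1:1 -> batch dominates in >= 18/20 seeds
  hits <- 0
  for (s in 1:20) {
    pv <- sim_pvca(s, sqrt(8), 1, 1)
    if (pv$e1 > pv$e4 && pv$e1 >= 0.6) hits <- hits + 1
  }
  expect_gte(hits, 18)

  # pure noise: residual is the largest component in >= 18/20 seeds
  hits <- 0
  for (s in 1:20) {
    pv <- sim_pvca(100 + s, 0, 0, 1)
    if (which.max(pv$proportions) == 4) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("silhouette matches the direct a/b formula and an independent oracle", {
  # 4-point two-batch geometry: s = (b - a)/max(a, b) by hand
  X <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
  rownames(X) <- paste0("s", 1:4)
  batch <- c("A", "A", "B", "B")
  b_val <- (10 + sqrt(101)) / 2
  expected <- (b_val - 1) / b_val
  expect_equal(eval_silhouette(X, batch), expected, tolerance = 1e-10)
  expect_equal(round(expected, 4), 0.9002)

  # independent reference implementation on random instances
  set.seed(82)
  for (i in 1:10) {
    n <- sample(12:30, 1)
    X <- matrix(rnorm(n * 3), n, 3, dimnames = list(paste0("s", 1:n), NULL))
    batch <- sample(rep(c("A", "B", "C"), length.out = n))
    while (min(table(batch)) < 2) batch <- sample(rep(c("A", "B", "C"), length.out = n))
    ref <- abs(mean(cluster::silhouette(as.integer(factor(batch)), dist(X))[, 3]))
    expect_equal(eval_silhouette(X, batch), ref, tolerance = 1e-10)
  }

  # overlapping identical clusters: negligible batch effect
  set.seed(83)
  X <- matrix(rnorm(40 * 2, 0, 0.1), 40, 2, dimnames = list(paste0("s", 1:40), NULL))
  expect_lt(eval_silhouette(X, rep(c("A", "B"), 20)), 0.1)
})

test_that("pcRegression is bounded, null-calibrated and tracks constructed variance", {
  set.seed(84)
  # batch labels independent of the data, n = 200
  mat <- matrix(rnorm(100 * 200), 100, 200,
                dimnames = list(paste0("g", 1:100), paste0("s", 1:200)))
  batch <- sample(rep(c("A", "B"), 100))
  e3 <- eval_pcregression(pca_embed(mat), batch)
  expect_lt(e3, 0.05)
  expect_gte(e3, 0)

  # constructed embedding: batch = sign of PC1, PC1 carries fraction f
  n <- 60
  pc1 <- c(rnorm(n / 2, -4), rnorm(n / 2, 4))
  scores <- cbind(pc1, matrix(rnorm(n * 9, 0, 1), n, 10 - 1))
  rownames(scores) <- paste0("s", 1:n)
  eig <- apply(scores, 2, var)
  f <- eig[1] / sum(eig)
  e3c <- eval_pcregression(scores, ifelse(pc1 < 0, "A", "B"), eigenvalues = eig)
  expect_lt(abs(e3c - f) / f, 0.1)
  expect_lte(e3c, 1)
})

test_that("batch-mixing entropy separates interleaved from split batches", {
  # interleaved lattice: near-perfect mixing
  n <- 60
  X <- cbind(seq_len(n), rep(0, n))
  rownames(X) <- sprintf("s%03d", seq_len(n))
  batch <- rep(c("A", "B"), n / 2)
  expect_gte(eval_entropy(X, batch, seed = 1), 0.95)

  # fully separated clusters: no mixing
  X2 <- cbind(c(seq_len(n / 2), 1000 + seq_len(n / 2)), rep(0, n))
  rownames(X2) <- sprintf("s%03d", seq_len(n))
  batch2 <- rep(c("A", "B"), each = n / 2)
  expect_lte(eval_entropy(X2, batch2, seed = 1), 0.05)

  # seeded determinism
  set.seed(85)
  X3 <- matrix(rnorm(200), 100, 2, dimnames = list(sprintf("s%03d", 1:100), NULL))
  b3 <- rep(c("A", "B"), 50)
  expect_identical(eval_entropy(X3, b3, seed = 7), eval_entropy(X3, b3, seed = 7))
})

test_that("highly variable genes capture inflated variance deterministically", {
  set.seed(86)
  G <- 300
  mat <- matrix(rnorm(G * 12, 5), G, 12,
                dimnames = list(sprintf("g%03d", 1:G), paste0("s", 1:12)))
  mat["g007", ] <- rnorm(12, 5, sqrt(10))   # 10x variance at the same mean
  hv <- detect_hvg(mat)
  expect_true("g007" %in% hv)
  expect_identical(hv, detect_hvg(mat))
  # n_top covering everything returns all genes
  expect_setequal(detect_hvg(mat, n_top = G), rownames(mat))
  expect_warning(detect_hvg(mat[1:20, ]), "all genes")
})

test_that("HVG conservation equals 1 for an identity correction of one experiment", {
  set.seed(87)
  mat <- matrix(rnorm(600 * 8, 5, 1 + rep(runif(600), 8)), 600, 8,
                dimnames = list(sprintf("g%03d", 1:600), paste0("s", 1:8)))
  expect_equal(eval_hvg_union(mat, list(mat)), 1)

  # destroying the signal with noise lowers conservation in >= 18/20 seeds
  hits <- 0
  for (s in 1:20) {
    set.seed(s)
    m <- matrix(rnorm(600 * 8, 5, 1 + rep(runif(600), 8)), 600, 8,
                dimnames = dimnames(mat))
    e_id <- eval_hvg_union(m, list(m[, 1:4], m[, 5:8]))
    noise <- matrix(rnorm(600 * 8), 600, 8, dimnames = dimnames(m))
    e_noise <- eval_hvg_union(noise, list(m[, 1:4], m[, 5:8]))
    if (e_noise < e_id) hits <- hits + 1
    expect_gte(e_noise, 0); expect_lte(e_id, 1)
  }
  expect_gte(hits, 18)
})

test_that("metrics are invariant to gene and sample order", {
  sim <- simulate_microarray_meta(sim_config(n_genes = 120,
                                             batches = c(A = 6, B = 6),
                                             seed = 88))
  meta <- sim_meta(sim)
  p <- list(matrix = meta$matrix, batch = unname(meta$batch),
            bio = unname(meta$bio))
  set.seed(89)
  gi <- sample(nrow(p$matrix)); si <- sample(ncol(p$matrix))
  q <- list(matrix = p$matrix[gi, si], batch = p$batch[si], bio = p$bio[si])

  e_p <- pca_embed(p$matrix); e_q <- pca_embed(q$matrix)
  expect_equal(eval_silhouette(e_p, p$batch), eval_silhouette(e_q, q$batch),
               tolerance = 1e-9)
  expect_equal(eval_pcregression(e_p, p$batch), eval_pcregression(e_q, q$batch),
               tolerance = 1e-9)
  expect_equal(eval_entropy(e_p, p$batch, seed = 3),
               eval_entropy(e_q, q$batch, seed = 3), tolerance = 1e-9)
  expect_setequal(detect_hvg(p$matrix), detect_hvg(q$matrix))
  pv_p <- eval_pvca(p$matrix, p$batch, p$bio)
  pv_q <- eval_pvca(q$matrix, q$batch, q$bio)
  expect_equal(pv_p$e1, pv_q$e1, tolerance = 1e-6)
})
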
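# Step-by-step empirical-Bayes oracle, coded independently with explicit
# batch-mean arithmetic and per-gene scalar iteration (no shared code with
# the package implementation).
combat_oracle <- function(mat, batch, tol = 1e-4, max_iter = 100) {
  batch <- factor(batch)
  G <- nrow(mat); N <- ncol(mat)
  lv <- levels(batch); n_i <- as.numeric(table(batch))
  bm <- sapply(lv, function(b) rowMeans(mat[, batch == b, drop = FALSE]))
  grand <- as.numeric(bm %*% (n_i / N))
  fitted <- bm[, as.integer(batch), drop = FALSE]
  varp <- rowSums((mat - fitted)^2) / N
  Z <- (mat - grand) / sqrt(varp)

  g_hat <- sapply(lv, function(b) rowMeans(Z[, batch == b, drop = FALSE]))
  d_hat <- sapply(lv, function(b) apply(Z[, batch == b, drop = FALSE], 1, var))
  g_star <- g_hat; d_star <- d_hat
  for (i in seq_along(lv)) {
    gbar <- mean(g_hat[, i]); t2 <- var(g_hat[, i])
    m <- mean(d_hat[, i]); s2 <- var(d_hat[, i])
    a <- (2 * s2 + m^2) / s2
    b <- (m * s2 + m^3) / s2
    ni <- n_i[i]
    Zi <- Z[, batch == lv[i], drop = FALSE]
    for (g in seq_len(G)) {
      go <- g_hat[g, i]; dn <- d_hat[g, i]
      repeat_count <- 0
      repeat {
        gn <- (ni * t2 * g_hat[g, i] + dn * gbar) / (ni * t2 + dn)
        dn2 <- (b + 0.5 * sum((Zi[g, ] - gn)^2)) / (ni / 2 + a - 1)
        change <- max(abs(gn - go) / abs(go), abs(dn2 - dn) / dn)
        go <- gn; dn <- dn2
        repeat_count <- repeat_count + 1
        if (change < tol || repeat_count >= max_iter) break
      }
      g_star[g, i] <- go; d_star[g, i] <- dn
    }
  }
  out <- Z
  for (i in seq_along(lv)) {
    idx <- batch == lv[i]
    out[, idx] <- (Z[, idx] - g_star[, i]) / sqrt(d_star[, i])
  }
  out <- out * sqrt(varp) + grand
  list(grand = grand, varp = varp, Z = Z, g_hat = g_hat, d_hat = d_hat,
       g_star = g_star, d_star = d_star, corrected = out)
}

test_that("parametric EB fit matches the step-by-step oracle on a fixed 5x12 matrix", {
  set.seed(101)
  mat <- matrix(rnorm(60, 8, 1.4), 5, 12,
                dimnames = list(paste0("g", 1:5), paste0("s", 1:12)))
  batch <- rep(c("A", "B"), each = 6)
  mat[, batch == "B"] <- mat[, batch == "B"] + 1.2

  meta <- list(matrix = mat, batch = batch)
  fit <- fit_combat(meta, mode = "parametric")
  orc <- combat_oracle(mat, batch)

  expect_equal(unname(fit$grand_mean), orc$grand, tolerance = 1e-6)
  expect_equal(unname(fit$var_pooled), unname(orc$varp), tolerance = 1e-6)
  expect_equal(unname(fit$gamma_hat), unname(orc$g_hat), tolerance = 1e-6)
  expect_equal(unname(fit$delta_hat), unname(orc$d_hat), tolerance = 1e-6)
  expect_equal(unname(fit$gamma_star), unname(orc$g_star), tolerance = 1e-6)
  expect_equal(unname(fit$delta_star), unname(orc$d_star), tolerance = 1e-6)
  expect_equal(apply_combat(meta, fit)$matrix, orc$corrected, tolerance = 1e-6)
})

test_that("both EB modes agree with the reference implementation", {
  meta <- rand_meta(60, c(8, 8), seed = 13, batch_shift = 1.5)
  par_ref <- suppressMessages(
    sva::ComBat(meta$matrix, batch = factor(meta$batch), par.prior = TRUE))
  expect_equal(correct_combat(meta, "parametric")$matrix, par_ref,
               tolerance = 1e-6, ignore_attr = TRUE)

  np_ref <- suppressMessages(
    sva::ComBat(meta$matrix, batch = factor(meta$batch), par.prior = FALSE))
  expect_equal(correct_combat(meta, "nonparametric")$matrix, np_ref,
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("correction is near-identity when no batch effect exists", {
  meta <- rand_meta(100, c(100, 100), seed = 21)
  res <- correct_combat(meta, "parametric")
  expect_lt(mean(abs(res$matrix - meta$matrix)), 0.05)
})

test_that("location shifts centred at +2 are removed", {
  # per-gene offsets, as the location/scale model assumes; a shift that is
  # exactly constant across genes would be indistinguishable from the prior
  # mean and the EB posterior would (correctly) leave per-gene noise behind
  meta <- rand_meta(100, c(100, 100), seed = 22)
  set.seed(220)
  shift <- rnorm(100, mean = 2, sd = 1)
  meta$matrix[, meta$batch == "b2"] <- meta$matrix[, meta$batch == "b2"] + shift
  res <- correct_combat(meta, "parametric")
  d <- rowMeans(res$matrix[, meta$batch == "b1"]) -
    rowMeans(res$matrix[, meta$batch == "b2"])
  expect_lt(mean(abs(d)), 0.05)
})

test_that("Q_ComBat is the exact composition of its two stages", {
  meta <- rand_meta(40, c(6, 6), seed = 31, batch_shift = 1)
  res <- correct_q_combat(meta)
  manual <- correct_combat(list(matrix = quantile_normalize(meta$matrix),
                                batch = meta$batch), "parametric")
  expect_identical(res$matrix, manual$matrix)

  # constant-quantile data (identical columns) pass through unchanged
  cmat <- matrix(rep(c(1, 5, 9, 2), 8), 4, 8,
                 dimnames = list(paste0("g", 1:4), paste0("s", 1:8)))
  suppressWarnings(res2 <- correct_q_combat(list(matrix = cmat,
                                                 batch = rep(c("A", "B"), each = 4))))
  expect_equal(res2$matrix, cmat, tolerance = 1e-6)
})

test_that("corrections preserve shape, labels and finiteness", {
  meta <- rand_meta(30, c(5, 5, 6), seed = 41, batch_shift = 1)
  for (res in list(correct_combat(meta, "parametric"),
                   correct_combat(meta, "nonparametric"),
                   correct_limma(meta),
                   correct_naive_ruv(meta, "empirical", k = 2))) {
    expect_identical(dimnames(res$matrix), dimnames(meta$matrix))
    expect_true(all(is.finite(res$matrix)))
  }
})
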
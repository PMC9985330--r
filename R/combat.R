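# Empirical-Bayes location/scale batch adjustment for (approximately)
# Gaussian log-scale expression, with parametric and non-parametric priors.
#
# Model per gene g, batch i, sample j:
#   Y_gij = alpha_g + X_j beta_g + gamma_gi + delta_gi * eps_gij
# Batch location (gamma) and scale (delta^2) effects are estimated on
# standardized data and shrunk toward a common batch prior before removal.

#' Fit the empirical-Bayes location/scale batch model
#'
#' Standardizes each gene with its grand mean (plus the biological-covariate
#' fit when `preserve_bio = TRUE`) and pooled variance, estimates per-batch
#' per-gene location and scale effects, and shrinks them by empirical Bayes.
#' `mode = "parametric"` places a normal prior on locations and an
#' inverse-gamma prior on squared scales, with method-of-moments
#' hyperparameters and a fixed-point iteration for the posteriors;
#' `mode = "nonparametric"` uses leave-one-gene-out likelihood-weighted
#' empirical posterior means.
#'
#' @inheritParams correct_limma
#' @param mode `"parametric"` or `"nonparametric"` empirical-Bayes prior.
#' @param tol convergence tolerance on the maximum relative change of the
#'   parametric fixed-point iteration.
#' @param max_iter iteration cap (a warning is raised when reached).
#' @return an object of class `combat_fit`.
#' @export
fit_combat <- function(meta, mode = c("parametric", "nonparametric"),
                       preserve_bio = FALSE, tol = 1e-4, max_iter = 100L) {
  mode <- match.arg(mode)
  p <- meta_parts(meta)
  mat <- p$matrix
  batch <- factor(p$batch)
  if (nlevels(batch) < 2) stop("need >= 2 batches")
  n_i <- as.numeric(table(batch))
  if (any(n_i < 2)) stop("every batch needs >= 2 samples")
  N <- ncol(mat)
  G <- nrow(mat)

  B <- stats::model.matrix(~ 0 + batch)
  design <- B
  if (preserve_bio) {
    if (is.null(p$bio) || length(unique(p$bio)) < 2)
      stop("preserve_bio requires a biological covariate with >= 2 categories")
    bio <- factor(p$bio)
    Xc <- stats::model.matrix(~ bio)[, -1, drop = FALSE]
    design <- cbind(B, Xc)
    if (qr(design)$rank < ncol(design))
      stop("rank-deficient design: batch confounded with biological covariate")
  }

  beta <- solve(crossprod(design), crossprod(design, t(mat)))  # p x G
  nb <- nlevels(batch)
  grand_mean <- drop((n_i / N) %*% beta[seq_len(nb), , drop = FALSE])  # length G
  fitted <- t(design %*% beta)
  var_pooled <- rowSums((mat - fitted)^2) / N
  low_var <- var_pooled < 1e-8
  if (any(low_var)) {
    warning("flooring ", sum(low_var), " pooled gene variance(s) at 1e-8")
    var_pooled[low_var] <- 1e-8
  }

  stand_mean <- matrix(grand_mean, G, N)
  if (preserve_bio)
    stand_mean <- stand_mean + t(design[, -seq_len(nb), drop = FALSE] %*%
                                   beta[-seq_len(nb), , drop = FALSE])
  Z <- (mat - stand_mean) / sqrt(var_pooled)

  gamma_hat <- matrix(NA_real_, G, nb, dimnames = list(rownames(mat), levels(batch)))
  delta_hat <- gamma_hat
  for (i in seq_len(nb)) {
    idx <- which(batch == levels(batch)[i])
    Zi <- Z[, idx, drop = FALSE]
    gamma_hat[, i] <- rowMeans(Zi)
    delta_hat[, i] <- row_vars(Zi)
  }
  zero_var <- delta_hat < 1e-8
  if (any(zero_var)) {
    warning("flooring ", sum(zero_var), " within-batch gene variance(s) at 1e-8")
    delta_hat[zero_var] <- 1e-8
  }

  gamma_star <- gamma_hat
  delta_star <- delta_hat
  prior <- vector("list", nb)

  for (i in seq_len(nb)) {
    idx <- which(batch == levels(batch)[i])
    Zi <- Z[, idx, drop = FALSE]
    g_hat <- gamma_hat[, i]
    d_hat <- delta_hat[, i]
    ni <- length(idx)

    if (mode == "parametric") {
      gbar <- mean(g_hat); t2 <- stats::var(g_hat)
      m <- mean(d_hat); s2 <- stats::var(d_hat)
      if (!is.finite(s2) || s2 < 1e-12) {
        # degenerate scale prior (all delta-hat equal): point mass at m
        a <- Inf; b <- Inf
        g_new <- (ni * t2 * g_hat + m * gbar) / (ni * t2 + m)
        prior[[i]] <- list(gamma_bar = gbar, tau2 = t2, a = a, b = b)
        gamma_star[, i] <- g_new
        delta_star[, i] <- m
        next
      }
      a <- (2 * s2 + m^2) / s2
      b <- (m * s2 + m^3) / s2
      g_old <- g_hat; d_old <- d_hat
      it <- 0L; change <- Inf
      while (change > tol && it < max_iter) {
        it <- it + 1L
        g_new <- (ni * t2 * g_hat + d_old * gbar) / (ni * t2 + d_old)
        sum2 <- rowSums((Zi - g_new)^2)
        d_new <- (b + 0.5 * sum2) / (ni / 2 + a - 1)
        change <- max(abs(g_new - g_old) / abs(g_old), abs(d_new - d_old) / d_old)
        g_old <- g_new; d_old <- d_new
      }
      if (it >= max_iter && change > tol)
        warning("batch ", levels(batch)[i],
                ": EB fixed-point iteration hit the cap, proceeding")
      prior[[i]] <- list(gamma_bar = gbar, tau2 = t2, a = a, b = b, iterations = it)
      gamma_star[, i] <- g_old
      delta_star[, i] <- d_old
    } else {
      post <- np_posterior(Zi, g_hat, d_hat)
      prior[[i]] <- list(nonparametric = TRUE)
      gamma_star[, i] <- post$gamma
      delta_star[, i] <- post$delta2
    }
  }
  names(prior) <- levels(batch)

  structure(
    list(mode = mode, preserve_bio = preserve_bio, batch_levels = levels(batch),
         grand_mean = grand_mean, stand_mean = stand_mean,
         var_pooled = var_pooled, gamma_hat = gamma_hat, delta_hat = delta_hat,
         gamma_star = gamma_star, delta_star = delta_star, prior = prior),
    class = "combat_fit"
  )
}

# Leave-one-gene-out likelihood-weighted posterior means, computed in blocks
# with a log-sum-exp guard. Zi: G x n standardized batch slice.
np_posterior <- function(Zi, g_hat, d_hat, block = 512L) {
  G <- nrow(Zi); n <- ncol(Zi)
  S1 <- rowSums(Zi); S2 <- rowSums(Zi^2)
  gamma <- numeric(G); delta2 <- numeric(G)
  base <- -0.5 * n * log(2 * pi * d_hat)  # per candidate gene g'
  for (start in seq(1L, G, by = block)) {
    rows <- start:min(start + block - 1L, G)
    # logw[g, g'] for g in rows: quadratic term expanded via sufficient stats
    quad <- outer(S2[rows], rep(1, G)) -
      2 * outer(S1[rows], g_hat) + n * matrix(g_hat^2, length(rows), G, byrow = TRUE)
    logw <- matrix(base, length(rows), G, byrow = TRUE) -
      quad / (2 * matrix(d_hat, length(rows), G, byrow = TRUE))
    logw[cbind(seq_along(rows), rows)] <- -Inf  # leave self out
    mx <- apply(logw, 1, max)
    w <- exp(logw - mx)
    sw <- rowSums(w)
    gamma[rows] <- (w %*% g_hat) / sw
    delta2[rows] <- (w %*% d_hat) / sw
  }
  list(gamma = gamma, delta2 = delta2)
}

#' Apply a fitted empirical-Bayes batch model
#'
#' Removes the shrunken batch location and scale effects from the standardized
#' data and restores each gene's original scale and (covariate-adjusted) mean.
#'
#' @inheritParams correct_limma
#' @param fit a `combat_fit` from [fit_combat()].
#' @return a `correction_result`.
#' @export
apply_combat <- function(meta, fit) {
  p <- meta_parts(meta)
  mat <- p$matrix
  batch <- factor(p$batch, levels = fit$batch_levels)
  Z <- (mat - fit$stand_mean) / sqrt(fit$var_pooled)
  out <- Z
  for (i in seq_along(fit$batch_levels)) {
    idx <- which(batch == fit$batch_levels[i])
    out[, idx] <- (Z[, idx, drop = FALSE] - fit$gamma_star[, i]) /
      sqrt(fit$delta_star[, i])
  }
  out <- out * sqrt(fit$var_pooled) + fit$stand_mean
  label <- if (fit$mode == "parametric") "ComBat1" else "ComBat2"
  correction_result(label, out, meta,
                    list(mode = fit$mode, preserve_bio = fit$preserve_bio))
}

#' One-call empirical-Bayes batch correction
#'
#' @inheritParams fit_combat
#' @return a `correction_result`.
#' @export
correct_combat <- function(meta, mode = c("parametric", "nonparametric"),
                           preserve_bio = FALSE) {
  apply_combat(meta, fit_combat(meta, mode = mode, preserve_bio = preserve_bio))
}

#' Quantile normalization followed by parametric empirical-Bayes correction
#'
#' @inheritParams correct_limma
#' @return a `correction_result` labelled `Q_ComBat`.
#' @export
correct_q_combat <- function(meta, preserve_bio = FALSE) {
  p <- meta_parts(meta)
  qmeta <- meta
  qmeta$matrix <- quantile_normalize(p$matrix)
  res <- correct_combat(qmeta, mode = "parametric", preserve_bio = preserve_bio)
  res$method <- "Q_ComBat"
  res$params$quantile_normalized <- TRUE
  res
}
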
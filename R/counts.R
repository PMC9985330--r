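# Count-native corrections for RNA-seq meta-experiments.

#' Log-CPM transform of a count meta-experiment
#'
#' Library-size-normalized `log2(counts-per-million + 1)`. This is the scale
#' on which the Gaussian corrections (limma, ComBat, RUV, MNN) operate when
#' the technology is RNA-seq.
#'
#' @param meta a count `meta_experiment` (or a bare count matrix).
#' @return numeric matrix of the same shape.
#' @export
log_transform_counts <- function(meta) {
  mat <- if (is.matrix(meta)) meta else meta_parts(meta)$matrix
  if (any(mat < 0)) stop("negative counts")
  lib <- colSums(mat)
  if (any(lib == 0)) stop("all-zero sample: ",
                          paste(colnames(mat)[lib == 0], collapse = ", "))
  log2(sweep(mat, 2, lib, "/") * 1e6 + 1)
}

# Vectorized Newton maximization of the NB log-likelihood over the size
# parameter r (in log space), one r per gene, given per-sample means mu.
# y, mu: G x n matrices. Falls back to a moment estimate where Newton fails.
nb_size_mle <- function(y, mu, max_iter = 50L, tol = 1e-6) {
  G <- nrow(y); n <- ncol(y)
  mbar <- rowMeans(mu)
  # pseudo-moment start: phi = sum((y-mu)^2 - mu) / sum(mu^2)
  phi0 <- rowSums((y - mu)^2 - mu) / rowSums(mu^2)
  phi0[!is.finite(phi0) | phi0 <= 0] <- 1e-8
  r <- 1 / pmin(pmax(phi0, 1e-8), 1e8)
  r <- pmin(pmax(r, 1e-8), 1e8)
  active <- rep(TRUE, G)
  for (it in seq_len(max_iter)) {
    if (!any(active)) break
    ra <- r[active]
    ya <- y[active, , drop = FALSE]
    mua <- mu[active, , drop = FALSE]
    rm_ <- matrix(ra, sum(active), n)
    d1 <- rowSums(digamma(ya + rm_) - digamma(rm_) + log(rm_) + 1 -
                    log(rm_ + mua) - (rm_ + ya) / (rm_ + mua))
    d2 <- rowSums(trigamma(ya + rm_) - trigamma(rm_) + 1 / rm_ -
                    1 / (rm_ + mua) - (mua - ya) / (rm_ + mua)^2)
    # Newton in psi = log r
    g <- ra * d1
    h <- ra * d1 + ra^2 * d2
    step <- ifelse(h < 0, g / h, sign(g) * -0.5)  # fallback fixed step uphill
    step <- pmin(pmax(step, -2), 2)
    psi <- log(ra) - step
    psi <- pmin(pmax(psi, log(1e-8)), log(1e8))
    r_new <- exp(psi)
    done <- abs(psi - log(ra)) < tol
    r[active] <- r_new
    active[active] <- !done
  }
  if (any(active)) {
    # non-convergent genes: moment fallback
    r[active] <- 1 / pmin(pmax(phi0[active], 1e-8), 1e8)
  }
  pmin(pmax(r, 1e-8), 1e8)
}

#' Negative-binomial quantile-matching batch correction for counts
#'
#' Fits a gene-wise negative-binomial batch model — batch-specific means (plus
#' biological-covariate effects in the full model) and batch-specific
#' dispersions — and maps every observed count through its batch-specific NB
#' cumulative distribution onto the quantile of a batch-free NB with pooled
#' mean and dispersion (covariate effects retained in the full model). Tied
#' count masses use the deterministic CDF midpoint `(F(c-1) + F(c))/2`.
#' Output counts are non-negative integers; genes with all-zero counts in any
#' batch are passed through unchanged.
#'
#' @inheritParams correct_limma
#' @param model `"null"` (batch only) or `"full"` (batch plus biological
#'   covariate). `"full"` without a usable covariate reduces to `"null"`.
#' @return a `correction_result` on the count scale.
#' @export
correct_combatseq <- function(meta, model = c("null", "full")) {
  model <- match.arg(model)
  p <- meta_parts(meta)
  mat <- p$matrix
  if (any(mat < 0) || !all(is_wholenumber(mat))) stop("requires integer counts")
  batch <- factor(p$batch)
  nb <- nlevels(batch)
  if (nb < 2) stop("need >= 2 batches")
  n_i <- as.numeric(table(batch))
  N <- ncol(mat); G <- nrow(mat)

  use_bio <- model == "full" && !is.null(p$bio) && length(unique(p$bio)) >= 2
  if (model == "full" && use_bio) {
    bio <- factor(p$bio)
    Xc <- stats::model.matrix(~ bio)[, -1, drop = FALSE]
    design <- cbind(stats::model.matrix(~ 0 + batch), Xc)
    if (qr(design)$rank < ncol(design))
      stop("confounded: batch and biological covariate are not separable")
  }

  # skip genes with an all-zero batch (degenerate batch distribution)
  batch_zero <- vapply(levels(batch), function(b)
    rowSums(mat[, batch == b, drop = FALSE]) == 0, logical(G))
  if (is.null(dim(batch_zero))) batch_zero <- matrix(batch_zero, nrow = G)
  skip <- rowSums(batch_zero) > 0
  out <- mat
  act <- which(!skip)
  if (!length(act)) {
    return(correction_result("ComBatseq", out, meta, list(model = model),
                             scale = "counts"))
  }
  y <- mat[act, , drop = FALSE]
  Ga <- length(act)

  # batch-specific per-sample means
  mu_b <- matrix(NA_real_, Ga, N)
  if (!use_bio) {
    for (b in levels(batch)) {
      idx <- which(batch == b)
      mu_b[, idx] <- rowMeans(y[, idx, drop = FALSE])
    }
    gamma <- log(vapply(levels(batch), function(b)
      rowMeans(y[, batch == b, drop = FALSE]), numeric(Ga)))
    if (is.null(dim(gamma))) gamma <- matrix(gamma, nrow = Ga)
    gamma_bar <- drop(gamma %*% (n_i / N))
    mu_free <- matrix(exp(gamma_bar), Ga, N)
  } else {
    # gene-wise Poisson IRLS for the log-linear mean structure
    mu_free <- matrix(NA_real_, Ga, N)
    nbcols <- nlevels(batch)
    for (gi in seq_len(Ga)) {
      fit <- suppressWarnings(
        stats::glm.fit(design, y[gi, ], family = stats::poisson(link = "log")))
      co <- fit$coefficients
      co[is.na(co)] <- 0
      eta_b <- drop(design %*% co)
      mu_b[gi, ] <- exp(eta_b)
      gbar <- sum(co[seq_len(nbcols)] * n_i / N)
      eta_free <- gbar +
        drop(design[, -seq_len(nbcols), drop = FALSE] %*% co[-seq_len(nbcols)])
      mu_free[gi, ] <- exp(eta_free)
    }
  }
  mu_b <- pmax(mu_b, 1e-8)
  mu_free <- pmax(mu_free, 1e-8)

  # batch-specific sizes, pooled dispersion = sample-size-weighted mean
  size_b <- matrix(NA_real_, Ga, N)
  phi_pool <- numeric(Ga)
  for (b in seq_len(nb)) {
    idx <- which(batch == levels(batch)[b])
    r_b <- nb_size_mle(y[, idx, drop = FALSE], mu_b[, idx, drop = FALSE])
    size_b[, idx] <- r_b
    phi_pool <- phi_pool + (n_i[b] / N) / r_b
  }
  size_pool <- 1 / pmin(pmax(phi_pool, 1e-8), 1e8)

  pl <- stats::pnbinom(y - 1, mu = mu_b, size = size_b)
  pu <- stats::pnbinom(y, mu = mu_b, size = size_b)
  pmid <- pmin(pmax((pl + pu) / 2, 1e-12), 1 - 1e-12)
  adj <- stats::qnbinom(pmid, mu = mu_free, size = matrix(size_pool, Ga, N))
  out[act, ] <- adj
  correction_result(if (model == "full") "ComBatseq_full" else "ComBatseq_null",
                    out, meta, list(model = model, used_bio = use_bio),
                    scale = "counts")
}

#' Replicate-based RUV correction for counts
#'
#' Treats samples sharing a biological category as replicates: on
#' `log(counts + 1)`, rows of the control-gene submatrix are centred within
#' each replicate group, the top-`k` left singular vectors of the centred
#' matrix give the unwanted-factor scores, and these are regressed out of all
#' genes (gene means preserved) before mapping back to rounded non-negative
#' counts. Requires at least one biological category spanning two batches.
#'
#' @inheritParams correct_limma
#' @param k number of unwanted factors.
#' @param controls control gene identifiers; default all genes.
#' @param replicate_groups optional named list mapping group name to sample
#'   ids, overriding the grouping derived from the biological covariate.
#' @return a `correction_result` on the count scale; `params$log_matrix`
#'   holds the corrected log-scale matrix before rounding.
#' @export
correct_ruvs <- function(meta, k = 1, controls = NULL, replicate_groups = NULL) {
  p <- meta_parts(meta)
  mat <- p$matrix
  if (any(mat < 0)) stop("requires counts")
  if (k < 1) stop("k must be >= 1")
  samples <- colnames(mat)

  if (is.null(replicate_groups)) {
    if (is.null(p$bio)) stop("no biological covariate to derive replicate groups")
    replicate_groups <- split(samples, p$bio)
  }
  spans <- vapply(replicate_groups, function(s)
    length(unique(p$batch[match(s, samples)])) >= 2, logical(1))
  if (!any(spans)) stop("no cross-batch replicates: every biological category ",
                        "is confined to a single batch")

  controls <- controls %||% rownames(mat)
  controls <- intersect(controls, rownames(mat))
  if (!length(controls)) stop("empty control set")

  L <- log(mat + 1)
  Zc <- t(L[controls, , drop = FALSE])      # samples x controls
  for (g in replicate_groups) {
    idx <- match(g, samples)
    Zc[idx, ] <- sweep(Zc[idx, , drop = FALSE], 2,
                       colMeans(Zc[idx, , drop = FALSE]))
  }
  sv <- svd(Zc)
  k_eff <- min(k, sum(sv$d > 1e-10))
  if (k_eff < 1) stop("replicate-centred matrix has no variation")
  W <- sv$u[, seq_len(k_eff), drop = FALSE] %*% diag(sv$d[seq_len(k_eff)], k_eff)

  mu <- rowMeans(L)
  Lc <- t(L - mu)                            # samples x genes, gene-centred
  alpha <- solve(crossprod(W), crossprod(W, Lc))
  L_out <- L - t(W %*% alpha)
  counts <- pmax(round(exp(L_out) - 1), 0)
  correction_result("RUVs", counts, meta,
                    list(k = k_eff, n_controls = length(controls),
                         log_matrix = L_out),
                    scale = "counts")
}
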
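# Evaluation metrics: each corrected matrix is scored with six quantities.
#   e1 PVCA batch proportion        (batch effect; lower is better)
#   e2 |mean silhouette| on batches (batch effect; lower is better)
#   e3 eigenvalue-weighted PC regression on batch (lower is better)
#   e4 PVCA biology proportion      (biology preserved; higher is better)
#   e5 normalized batch-mixing entropy (higher is better)
#   e6 conserved highly-variable-gene ratio (higher is better)

#' Principal-component embedding of samples
#'
#' Genes are mean-centred, then the sample scores, eigenvalues and variance
#' proportions are obtained from the singular value decomposition. At most
#' `min(n_components, samples - 1, genes)` components are retained;
#' proportions are relative to the total variance of the matrix.
#'
#' @param mat gene-by-sample numeric matrix with >= 3 samples.
#' @param n_components maximum number of components (default 20).
#' @return object of class `pca_embedding` with `scores` (samples x
#'   components), `eigenvalues`, `proportion` and `total_variance`.
#' @export
pca_embed <- function(mat, n_components = 20) {
  if (ncol(mat) < 3) stop("need >= 3 samples")
  Xc <- mat - rowMeans(mat)
  if (all(abs(Xc) < 1e-12)) stop("zero variance: constant matrix")
  k <- min(n_components, ncol(mat) - 1, nrow(mat))
  sv <- svd(t(Xc))
  eig_all <- sv$d^2 / (ncol(mat) - 1)
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  rownames(scores) <- colnames(mat)
  structure(
    list(scores = scores, eigenvalues = eig_all[seq_len(k)],
         proportion = eig_all[seq_len(k)] / sum(eig_all),
         total_variance = sum(eig_all)),
    class = "pca_embedding"
  )
}

#' @export
print.pca_embedding <- function(x, ...) {
  cat("<pca_embedding> ", nrow(x$scores), " samples x ", ncol(x$scores),
      " components; leading proportions: ",
      paste(sprintf("%.3f", utils::head(x$proportion, 5)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# ANOVA-style moment fallback for one PC: proportions from type-I sums of
# squares of batch, bio and their interaction.
pvca_moment_fallback <- function(y, batch, bio) {
  fit <- stats::aov(y ~ batch * bio)
  ss <- summary(fit)[[1]][["Sum Sq"]]
  terms <- rownames(summary(fit)[[1]])
  v <- c(batch = 0, bio = 0, `batch:bio` = 0, resid = 0)
  v["batch"] <- sum(ss[grepl("^batch *$", terms)])
  v["bio"] <- sum(ss[grepl("^bio *$", terms)])
  v["batch:bio"] <- sum(ss[grepl("^batch:bio", terms)])
  v["resid"] <- sum(ss[grepl("Residuals", terms)])
  v / sum(v)
}

#' Principal variance component analysis
#'
#' PCA followed by a per-component random-effects decomposition: for each
#' retained PC a mixed model with random intercepts for batch, biology and
#' their interaction is fitted by REML, and the per-factor variance
#' proportions are averaged across PCs with eigenvalue weights. PCs are
#' retained until the cumulative variance reaches `threshold` (minimum
#' `min_pc`). If a REML fit fails, an ANOVA-type moment estimator is used for
#' that component.
#'
#' @param mat gene-by-sample matrix.
#' @param batch,bio per-sample factors, each with >= 2 levels.
#' @param threshold cumulative-variance cutoff for PC retention (default 0.6).
#' @param min_pc minimum number of PCs (default 3).
#' @param n_components maximum PCs considered (default 20).
#' @return list with `e1` (batch proportion), `e4` (biology proportion),
#'   `proportions` (weighted-average proportions over factors, sums to 1) and
#'   `per_pc` (component-by-factor table).
#' @export
eval_pvca <- function(mat, batch, bio, threshold = 0.6, min_pc = 3,
                      n_components = 20) {
  batch <- factor(batch); bio <- factor(bio)
  if (nlevels(batch) < 2) stop("batch is constant across samples")
  if (nlevels(bio) < 2) stop("biological factor is constant across samples")
  emb <- pca_embed(mat, n_components)
  cum <- cumsum(emb$proportion)
  npc <- which(cum >= threshold)[1]
  if (is.na(npc)) npc <- length(cum)
  npc <- min(max(npc, min_pc), ncol(emb$scores))

  per_pc <- matrix(NA_real_, npc, 4,
                   dimnames = list(paste0("PC", seq_len(npc)),
                                   c("batch", "bio", "batch:bio", "resid")))
  for (i in seq_len(npc)) {
    y <- emb$scores[, i]
    props <- tryCatch({
      fit <- suppressMessages(suppressWarnings(
        lme4::lmer(y ~ (1 | batch) + (1 | bio) + (1 | batch:bio),
                   REML = TRUE,
                   control = lme4::lmerControl(
                     calc.derivs = FALSE,
                     check.conv.singular = lme4::.makeCC(action = "ignore",
                                                         tol = 1e-4)))))
      vc <- as.data.frame(lme4::VarCorr(fit))
      v <- c(batch = vc$vcov[vc$grp == "batch"],
             bio = vc$vcov[vc$grp == "bio"],
             `batch:bio` = vc$vcov[vc$grp == "batch:bio"],
             resid = vc$vcov[vc$grp == "Residual"])
      v / sum(v)
    }, error = function(e) pvca_moment_fallback(y, batch, bio))
    per_pc[i, ] <- props
  }
  w <- emb$eigenvalues[seq_len(npc)]
  avg <- colSums(per_pc * w) / sum(w)
  list(e1 = unname(avg["batch"]), e4 = unname(avg["bio"]),
       proportions = avg, per_pc = per_pc, n_pcs = npc)
}

#' Absolute mean silhouette width over batches
#'
#' The standard silhouette `s(i) = (b - a)/max(a, b)` with batch labels as
#' clusters and Euclidean distance in the PC embedding; the score is
#' `|mean(s)|`, near 0 for negligible batch effect and near 1 for strong
#' batch separation.
#'
#' @param embedding a [pca_embed()] result (or a samples-by-coordinates
#'   matrix).
#' @param batch per-sample batch labels; >= 2 batches, each with >= 2 samples.
#' @return scalar in \[0, 1\].
#' @export
eval_silhouette <- function(embedding, batch) {
  X <- if (inherits(embedding, "pca_embedding")) embedding$scores else embedding
  batch <- factor(batch)
  if (nlevels(batch) < 2) stop("need >= 2 batches")
  if (any(table(batch) < 2)) stop("every batch needs >= 2 samples")
  D <- as.matrix(stats::dist(X))
  n <- nrow(X)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(batch == batch[i])
    a <- mean(D[i, setdiff(own, i)])
    b <- min(vapply(setdiff(levels(batch), as.character(batch[i])),
                    function(l) mean(D[i, batch == l]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  abs(mean(s))
}

#' Eigenvalue-weighted principal-component regression on batch
#'
#' For each retained PC, the one-way R-squared of the scores on the batch
#' factor is computed; the score is the eigenvalue-weighted average
#' `sum(lambda_i R2_i) / sum(lambda_i)` over the available (top 20) PCs.
#'
#' @inheritParams eval_silhouette
#' @param eigenvalues PC variances; taken from the embedding when it is a
#'   `pca_embedding`.
#' @return scalar in \[0, 1\].
#' @export
eval_pcregression <- function(embedding, batch, eigenvalues = NULL) {
  if (inherits(embedding, "pca_embedding")) {
    X <- embedding$scores
    eigenvalues <- embedding$eigenvalues
  } else X <- embedding
  batch <- factor(batch)
  if (nlevels(batch) < 2) stop("batch is constant")
  if (is.null(eigenvalues)) eigenvalues <- apply(X, 2, stats::var)
  r2 <- vapply(seq_len(ncol(X)), function(i) {
    y <- X[, i]
    tot <- sum((y - mean(y))^2)
    if (tot < 1e-300) return(0)
    gm <- tapply(y, batch, mean)
    between <- sum(table(batch) * (gm - mean(y))^2)
    between / tot
  }, numeric(1))
  sum(eigenvalues * r2) / sum(eigenvalues)
}

#' Regional entropy of batch mixing
#'
#' For a seeded random subset of samples, the Shannon entropy of the batch
#' composition among each sample's `k_neighbours` nearest neighbours in the
#' PC1-PC2 plane is averaged and normalized by `log(number of batches)`, so
#' perfect mixing scores 1 regardless of batch count. Samples are
#' canonically sorted by id before seeding, making the score invariant to
#' input order.
#'
#' @inheritParams eval_silhouette
#' @param n_queries number of query samples (default `min(100, n)`).
#' @param k_neighbours neighbourhood size (default `min(15, n - 1)`).
#' @param seed RNG seed for the query draw.
#' @return scalar in \[0, 1\].
#' @export
eval_entropy <- function(embedding, batch, n_queries = NULL, k_neighbours = NULL,
                         seed = 1) {
  X <- if (inherits(embedding, "pca_embedding")) embedding$scores else embedding
  n <- nrow(X)
  if (n < 4) stop("need >= 4 samples")
  if (ncol(X) < 2) stop("need >= 2 components")
  batch <- factor(batch)
  ids <- rownames(X) %||% as.character(seq_len(n))
  ord <- order(ids)
  X <- X[ord, 1:2, drop = FALSE]
  batch <- batch[ord]

  nq <- min(n_queries %||% min(100, n), n)
  k <- min(k_neighbours %||% 15, n - 1)
  queries <- with_seed(seed, sample.int(n, nq))
  D <- as.matrix(stats::dist(X))
  nb_levels <- nlevels(batch)
  h <- vapply(queries, function(q) {
    nbrs <- order(D[q, ])[2:(k + 1)]      # self is at distance 0
    p <- tabulate(batch[nbrs], nbins = nb_levels) / k
    p <- p[p > 0]
    -sum(p * log(p))
  }, numeric(1))
  mean(h) / log(nb_levels)
}

#' Detect highly variable genes
#'
#' Fits a quadratic least-squares trend of per-gene variance on per-gene mean
#' (on the analysis scale); the HVG score is the observed variance minus the
#' trend, and the top `n_top` genes are returned. The default `n_top` is
#' `max(50, min(1000, 10%` of genes`))`; when the matrix holds fewer genes
#' than the minimum, all genes are returned with a warning.
#'
#' @param mat gene-by-sample matrix with >= 4 samples.
#' @param n_top number of genes to return.
#' @return character vector of gene identifiers.
#' @export
detect_hvg <- function(mat, n_top = NULL) {
  if (ncol(mat) < 4) stop("need >= 4 samples")
  G <- nrow(mat)
  n_top <- n_top %||% max(50, min(1000, floor(0.1 * G)))
  if (n_top >= G) {
    if (G < 50) warning("fewer genes than the HVG minimum; returning all genes")
    return(rownames(mat))
  }
  mu <- rowMeans(mat)
  v <- row_vars(mat)
  trend <- stats::lm(v ~ mu + I(mu^2))
  score <- v - stats::fitted(trend)
  ord <- order(-score, rownames(mat))
  rownames(mat)[ord[seq_len(n_top)]]
}

#' Conserved highly-variable-gene ratio
#'
#' `e6 = |HVG(corrected) intersect U| / |U|` where `U` is the union of the
#' per-experiment HVG sets computed on the shared gene space.
#'
#' @param corrected corrected gene-by-sample matrix (analysis scale).
#' @param experiment_mats list of per-experiment matrices restricted to the
#'   shared genes (the uncorrected meta-experiment split by batch).
#' @param n_top per-call HVG count passed to [detect_hvg()].
#' @return scalar in \[0, 1\].
#' @export
eval_hvg_union <- function(corrected, experiment_mats, n_top = NULL) {
  U <- unique(unlist(lapply(experiment_mats, detect_hvg, n_top = n_top)))
  if (!length(U)) stop("empty HVG union")
  length(intersect(detect_hvg(corrected, n_top), U)) / length(U)
}
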
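---
title: "Benchmarking batch-correction methods for bulk transcriptome meta-experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking batch-correction methods for bulk transcriptome meta-experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Public repositories hold thousands of bulk transcriptome experiments —
microarray log-intensities and RNA-seq counts — that become far more valuable
when pooled. Pooling, however, mixes biological signal with *batch effects*:
systematic non-biological differences between studies (platform, lab, run).
Many batch-correction methods (BCMs) exist, each with different assumptions,
and no single method wins on every data set. `bcmrank` builds a
*meta-experiment* from several studies, applies a panel of BCMs implemented
from first principles, scores every corrected matrix with six complementary
metrics, and aggregates the scores by dense ranking into a single
recommendation (*sumRank*). The uncorrected data always participate as a
baseline, so "do nothing" is a possible answer.

## Meta-experiment assembly

Studies are linked through a user-designated biological covariate: two
experiments are connected when they share at least one category (e.g. both
contain rheumatoid-arthritis samples). Experiments outside the largest
connected component are filtered out — without shared biology there is no
anchor to separate batch from signal. Component ties are broken by total
sample count, then lexicographic id, so assembly is deterministic and
invariant to input order. The retained studies are merged over the
*intersection* of their gene sets (a union would create block-missing data
that every downstream method would have to impute); the fraction of genes
lost is logged because small shared gene pools are the main practical risk of
this design. Sample ids duplicated across studies are disambiguated with the
experiment-id prefix. Each sample's batch label is its source experiment.

## The correction panel

All corrections are authored in the package; external reference
implementations are used only as cross-checks in the test suite.

**Gaussian (log-scale) methods.** For microarray input these operate on the
matrix as given (assumed log-normalized); for RNA-seq they operate on
`log2(CPM + 1)`.

* `limma` — gene-wise least squares on an intercept plus sum-to-zero batch
  contrasts (optionally protecting the biological factor); the fitted batch
  component is subtracted. Exact for purely additive offsets.
* `ComBat1` / `ComBat2` — the empirical-Bayes location/scale model
  `Y = alpha + X beta + gamma_batch + delta_batch * eps`. Genes are
  standardized by grand mean and pooled variance; per-batch per-gene
  location (`gamma`) and scale (`delta^2`) estimates are shrunk either with
  parametric priors (normal on `gamma`, inverse-gamma on `delta^2`,
  method-of-moments hyperparameters, fixed-point iteration to a 1e-4
  maximum relative change, 100-iteration cap) or non-parametrically
  (leave-one-gene-out likelihood-weighted posterior means, computed with a
  log-sum-exp guard). `Q_ComBat` quantile-normalizes first, then applies the
  parametric adjustment. Within-batch variances are floored at 1e-8 with a
  warning so constant genes cannot produce infinities.
* `naiveRandRUV_*` — remove-unwanted-variation: the top-`k` left singular
  vectors of the (gene-centred) sample-by-control submatrix are removed from
  all genes by ridge regression `(W'W + nu I)^-1 W'Y`. Controls are either a
  packaged list of human housekeeping symbols or the `max(100, 5%)` least
  variable genes after within-batch centring. Genes are mean-centred before
  the factor estimation and the means restored afterwards; without centring
  the first singular vector is the mean expression profile and removing it
  destroys the data. Defaults `k = 2`, `nu = 0.01 * mean(d)^2` where `d` are
  the control singular values — the scale-aware analogue of a unit ridge.
  Quantile-combined variants (`Q_*`) normalize first.
* `mnnCorrect` — mutual nearest neighbours. Samples are cosine-normalized
  for pair finding; batches merge sequentially in id order; each pair
  contributes the vector (reference − target) *on the original scale*; a
  target sample's correction is the Gaussian-kernel average of pair vectors,
  with the kernel acting on both the sample-to-pair distance and the pair's
  own span (bandwidth `sigma = 0.1` on the normalized scale). The span term
  down-weights wide, unreliable pairs; it is what makes a batch that is an
  exact shifted copy of the reference collapse onto it essentially exactly.
  The reference batch is never modified. Default `k = 20`, capped at the
  smallest batch size minus one.

**Count-native methods (RNA-seq only).**

* `ComBatseq_null` / `ComBatseq_full` — a negative-binomial analogue of the
  location/scale model. Per gene, batch-specific NB means (group means in
  the null model; a gene-wise log-linear fit with batch indicators plus the
  biological covariate in the full model) and batch-specific dispersions
  (vectorized Newton iterations on the NB log-likelihood in `log(size)`
  space, moment-estimator start and fallback, floors at 1e-8) are
  estimated. Each count is pushed through its batch CDF at the midpoint
  `(F(c-1) + F(c))/2` — a deterministic tie rule — and inverted on the
  batch-free NB whose mean pools the batch effects (covariate effects are
  retained in the full model) and whose dispersion is the sample-size
  weighted pool. Outputs are non-negative integers. Genes with all-zero
  counts in *any* batch pass through unchanged: a zero batch mean makes
  that batch's CDF degenerate and any mapping would hallucinate counts. No
  library-size offset is used; sequencing-depth differences between batches
  are treated as part of the batch effect.
* `RUVs` — replicate-based RUV on `log(counts + 1)`: samples sharing a
  biological category act as replicates, rows are centred within each
  category, the top-`k` singular vectors of the centred control-gene matrix
  are the unwanted factors, and they are regressed out of all genes before
  mapping back to rounded non-negative counts. At least one category must
  span two batches, otherwise unwanted and wanted variation are not
  separable. Defaults: `k = 1`, controls = all genes.

A plugin hook (`external =` in `run_pipeline()`) injects matrices corrected
by methods outside the panel (e.g. distance-based optimizers) into the
evaluation and ranking stages.

## The six metrics

All metrics are computed on the log analysis scale (counts are log-CPM
transformed first) from a gene-centred PCA of at most 20 components.

* **e1 / e4 — variance-component proportions.** PCA is followed by a
  per-component random-effects decomposition (batch, biology, and their
  interaction as random intercepts, REML via `lme4`; an ANOVA moment
  estimator backs up failed fits). Components are retained until 60%
  cumulative variance (minimum 3) — the convention of the variance-component
  tooling this follows; per-factor proportions are averaged with eigenvalue
  weights. e1 is the batch proportion (lower is better), e4 the biology
  proportion (higher is better).
* **e2 — |mean silhouette| with batches as clusters**, Euclidean distance in
  PC space. PC space rather than gene space keeps the metric fast and
  noise-robust; the absolute value is used because strong *negative*
  structure is also a sign of batch trouble. Lower is better.
* **e3 — eigenvalue-weighted PC regression.** Per component, the one-way R²
  of scores on batch; weighted by eigenvalues and normalized by the top-20
  variance. R² weighting only — no per-component significance filter — keeps
  the score deterministic. Lower is better.
* **e5 — regional batch-mixing entropy.** For up to 100 seeded query
  samples, the Shannon entropy of the batch composition among the
  `min(15, n-1)` nearest neighbours in the PC1–PC2 plane, normalized by
  `log(B)` so perfect mixing is 1 for any batch count. Samples are sorted by
  id before seeding, making the draw order-invariant; the pipeline derives
  the seed from its top-level seed. Higher is better.
* **e6 — highly-variable-gene conservation.** HVGs are genes whose variance
  exceeds a quadratic least-squares mean–variance trend (deterministic, no
  loess smoothing); the score is the fraction of the union of per-experiment
  HVG sets that remains highly variable after correction. Higher is better.

## Ranking

e1–e3 are negated and dense-ranked; e4–e6 are dense-ranked directly — rank 1
always means best. sumRank is the dense ascending rank of the six-rank sum;
ties persist (no secondary tie-break) and tied methods are listed
alphabetically. Dense ranking makes the aggregation invariant to any
monotone rescaling of a metric column, which is the point: the six raw
scores live on incomparable scales.

## The simulator

`simulate_microarray_meta()` draws gene baselines from `N(7, 1.5^2)`
(typical log2 intensity range), adds a 1-unit condition effect to 10% of
genes, and applies per-batch per-gene location offsets `N(0, 1)` and noise
scale factors `LogNormal(0, 0.3^2)` to all genes over `N(0, 0.5^2)` noise —
exactly the location/scale generative model, with the exact batch-free
matrix stored as ground truth. `simulate_count_meta()` draws NB counts with
log-normal base means (meanlog 4, sdlog 1.2, dispersion 0.15), a 2-fold
batch mean shift and 1.5x dispersion multiplier on affected genes in
non-reference batches. These defaults are the study conditions of the test
suite; what the simulator does *not* emulate is gene–gene correlation,
platform-specific intensity saturation, or outlier samples — passing tests
therefore demonstrate correctness of the machinery and sensible behaviour
under the assumed models, not performance guarantees on arbitrary real data.

## Numerical choices and degenerate inputs

* Zero variances (pooled or within batch) are floored at 1e-8 with a
  warning rather than erroring, so constant genes survive.
* A gene-constant batch shift is indistinguishable from the EB prior mean;
  the posterior then correctly shrinks to the common shift and leaves
  per-gene sampling noise in place. Tests of shift removal therefore use
  gene-varying offsets, which is what the model assumes.
* Quantile-normalization ties receive the mean of the reference order
  statistics over the tied span — deterministic, no random jitter.
* Dense ranks are computed by matching against the sorted unique values;
  HVG ties break lexicographically by gene id.
* All pipeline randomness (only the entropy query draw) derives from the
  single top-level seed, so reruns are byte-identical.

## Problem sizes

The test suite and the acceptance script run simulations of 120–500 genes,
2–3 batches and 8–100 samples per batch, with 10–20 seed replicates for the
stochastic properties. These sizes were chosen so that every documented
property is measurable (law-of-large-numbers checks use the larger sample
counts) while a full run stays comfortable on a laptop; the generative
models contain nothing scale-dependent.

## Known limitations

* Linking uses a single designated covariate; multi-covariate linking is a
  noted extension.
* PC-regression uses R² weighting without a significance filter, a
  simplification of the kNN-based rejection-rate statistic it approximates.
* The full-model count correction fits means by Poisson IRLS (a
  quasi-likelihood approximation to the NB mean fit); the null model uses
  exact NB group-mean MLEs.
* Housekeeping-gene controls apply to human symbols only; other species
  should use empirical controls or a replacement list.
* No quality control of the input experiments is performed; inputs are
  assumed pre-processed and QC'ed.
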
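Package: bcmrank
Title: Benchmark and Rank Batch-Correction Methods for Bulk Transcriptome
    Meta-Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assembles multiple bulk transcriptome experiments (microarray
    log-intensities or RNA-seq counts) into a single meta-experiment, applies a
    suite of batch-correction methods implemented from first principles
    (quantile normalization, limma-style linear removal, parametric and
    non-parametric empirical-Bayes location/scale adjustment, quantile-combined
    variants, remove-unwanted-variation with housekeeping or empirical control
    genes, negative-binomial quantile-matching count correction, replicate-based
    RUV, and mutual-nearest-neighbour correction), scores every corrected matrix
    with six batch-effect and biology-preservation metrics (principal variance
    component analysis, silhouette, principal-component regression, batch-mixing
    entropy, and highly-variable-gene conservation), and aggregates the scores
    by dense ranking into a final per-method prioritization. Includes a
    synthetic meta-experiment generator with known ground truth and an
    end-to-end pipeline with a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    jsonlite,
    lme4,
    stats,
    utils
Suggests:
    cluster,
    limma,
    optparse,
    sva,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
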
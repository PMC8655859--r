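Package: perewas
Title: Multi-Tissue Perinatal DNA Methylation Association Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for epigenome-wide association studies of
    neurodevelopmental outcomes using Illumina 450k-style methylation beta
    values from perinatal tissues (cord blood, maternal blood, placenta).
    Provides probe and sample quality control, reference-based cell-type
    deconvolution by constrained non-negative least squares, surrogate
    variable estimation with genomic-inflation-guided model selection,
    site-wise linear models with empirical-Bayes variance moderation and
    false discovery rate control, global and region-stratified methylation
    tests including a permutation test on methylation cumulative density
    functions, multi-threshold risk-gene enrichment curves with random
    gene-set permutation controls, probe-count-bias-adjusted gene ontology
    testing via the Wallenius noncentral hypergeometric distribution, and a
    synthetic-data generator with known ground truth (cell mixtures, latent
    batch factors, sex effects, spiked risk-gene signal) so that every stage
    has a recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    sva,
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
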
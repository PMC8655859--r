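---
title: "Methods behind perewas: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind perewas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perewas)
```

## The scientific setting

`perewas` implements an epigenome-wide association workflow for Illumina
450k-style DNA methylation beta values measured in perinatal tissues (cord
blood, maternal blood during pregnancy, placenta) and compared against a
three-level 36-month neurodevelopmental outcome: typically developing (TD),
non-typically developing (nonTD), and autism spectrum disorder (ASD). The
primary contrast is ASD versus TD; nonTD versus TD is the sensitivity
contrast, fit by dropping the excluded group rather than dummy-coding it.

Cohorts of this size (roughly 100–150 samples) are underpowered for
genome-wide-significant single-CpG discovery. The workflow therefore
emphasizes aggregate inference: calibrated site-wise tests, global and
region-stratified methylation summaries, and — the headline analysis —
enrichment of nominally associated CpGs in a curated autism risk-gene set,
evaluated over a grid of significance thresholds with random-gene-set
permutation controls and a probe-count-bias-corrected ontology test.

## Stage-by-stage model

### Quality control

Probes are removed when their detection p-value exceeds 0.01 in strictly
more than 10% of samples (both inequalities strict, so a probe failing in
exactly 10% of samples is retained), then listed cross-reactive probes are
dropped. Samples are removed for mean log2 array intensity below 10.5, a
failed-detection fraction above 20%, or a mismatch between recorded sex and
methylation-predicted sex. The intensity summary is taken as an input column
rather than derived from raw intensities, which are out of scope. Sex is
predicted from the per-sample difference (median chrY beta − median chrX
beta), split by a deterministic one-dimensional 2-means whose centers are
initialized at the minimum and maximum; the cluster with the larger mean is
called male. With no X/Y probes the check is skipped and flagged in the QC
report.

### Cell-type deconvolution

Bulk methylation is modeled as a nonnegative mixture of reference cell-type
profiles. For each sample we solve

$$\hat w = \arg\min_w \|y - R^\top w\|^2 \quad \text{s.t. } w \ge 0,\ \sum_k w_k \le 1$$

by active-set nonnegative least squares. The inequality sum constraint
(rather than equality) lets unmodeled cell types absorb residual mass; it is
imposed by augmenting the design with a slack column and a heavily weighted
sum-to-one row, so the solver itself stays a plain NNLS and the result is
deterministic. Estimated proportions are reported raw, without
renormalization to sum to one, and the choice is deliberate: renormalizing
would hide the mass assigned to the slack and change the covariate scale.
Discriminating probes are chosen per cell type as the largest and smallest
one-vs-rest mean differences, ties broken by probe id so selection does not
depend on input order.

### Surrogate variables

Latent structure (batch, cell composition drift, other unmodeled variation)
is estimated by iteratively reweighted surrogate variable analysis. The data
are residualized on the full model containing the diagnosis term; the top
right-singular vectors of the residuals seed the candidates. Each iteration
computes, per probe, (a) the probability of association with the candidate
surrogate variables and (b) the probability of *no* association with
diagnosis given those candidates, via a density-based local false discovery
rate on the respective F-test p-values, multiplies the two into a probe
weight, and recomputes the SVD of the row-weighted centered data matrix.
Conditioning (b) on the current candidates is essential: it lets probes that
load on an outcome-correlated confounder keep weight, so the surrogate
variables can absorb confounder–outcome overlap while genuinely
outcome-driven probes are down-weighted (the protection property).

Surrogate variables are estimated on M-values,
$M = \log_2(\beta/(1-\beta))$, where latent effects act nearly linearly;
on the bounded beta scale the logistic squashing attenuates factor loadings
at extreme methylation levels and degrades recovery. Site-wise effect
estimates remain on the beta scale (percent methylation differences), which
is the interpretable reporting scale.

**Choosing the number of surrogate variables.** For k = 0..K the site-wise
model with the first k surrogate variables yields diagnosis p-values, and
the genomic inflation factor

$$\lambda(k) = \mathrm{median}\{\chi^2_1\text{-quantile of } (1-p)\}/0.4549$$

is computed. We select the *smallest* k whose $|\lambda(k)-1|$ lies within
`tol = 0.1` of the best value achieved. A strict argmin would be decided by
Monte-Carlo noise once calibration is reached — every k at or beyond the
true factor count gives $\lambda \approx 1$ — so the tolerance band is what
operationalizes "closest to 1.0 with preference for fewer surrogate
variables". An exact tie still resolves to the smaller k, and k = 0 is an
admissible selection. Defaults: K max 10, 5 reweighting iterations; the
recovery simulations in the test suite use 8 iterations, where the probe
weights have visibly converged.

### Site-wise association and moderation

Per probe, ordinary least squares of methylation on intercept, diagnosis
indicator and adjustment terms (surrogate variables, or a known-covariate
design in the sensitivity model; samples with missing covariates are dropped
per model). Residual variances $s_j^2$ with $d$ degrees of freedom are
shrunk toward a scaled inverse-chi-square prior fit by matching the moments
of $\log s^2$ (digamma/trigamma relations), giving hyperparameters $d_0$ and
$s_0^2$ and posterior variances

$$\tilde s_j^2 = \frac{d_0 s_0^2 + d\, s_j^2}{d_0 + d},$$

with moderated t-statistics on $d_0 + d$ degrees of freedom and two-sided
p-values. With homogeneous variances the fit degenerates gracefully
($d_0 = \infty$, posterior equal to the common value). The implementation
agrees with the standard microarray empirical-Bayes machinery to numerical
precision, which the test suite verifies against an independent
implementation. Benjamini–Hochberg q-values accompany every result table.
Effects are reported as ASD − TD differences in percent methylation
(coefficient × 100).

### Global methylation

Per-sample means over all autosomal probes and within island / shore /
shelf / open-sea strata (a disjoint, exhaustive partition: N/S shores and
shelves collapse, absent island relation means open sea) plus the enhancer
flag, which deliberately stays an overlapping annotation as in the array
manifest rather than a fifth exclusive stratum. Group differences per
stratum come from linear models with surrogate-variable adjustment,
optionally sex-stratified (strata with fewer than three samples per group
are skipped). A distribution-level test complements the means: each sample
contributes its empirical CDF over stratum probes on a fixed grid of 101
equally spaced beta values; the statistic is the mean absolute difference
between group-averaged CDFs, and significance comes from group-label
permutation with $p = (1 + \#\{perm \ge obs\})/(1 + n_{perm})$, which is
valid (never anti-conservative) by construction and bounded below by
$1/(n_{perm}+1)$.

### Risk-gene enrichment

CpGs map to genes by splitting the manifest's semicolon-separated symbols
(deduplicated per probe, matched case-sensitively). The gene universe is
every symbol with at least one analyzed CpG. At each threshold in the grid
(0.0001, 0.001, 0.005, 0.01, 0.02, 0.03, 0.04, 0.05, 0.1, 0.15, 0.2, 0.3,
0.5, 0.7, 0.99) a gene is "selected" if any of its CpGs has p strictly below
the threshold, and the gene-level 2×2 table (risk × selected) is tested with
the Pearson chi-square without continuity correction — the choice that
reproduces printed worked-example arithmetic — alongside the expected
overlap (margin product over universe size). Negative controls repeat the
whole curve for `n_perm = 10` random gene sets of the same size drawn
uniformly without replacement from the universe under a fixed seed; uniform
(rather than probe-count-matched) sampling is the implemented scheme. An
optional probe restriction (e.g. to meQTL-target CpGs) subsets the results
first and rebuilds the universe, and restricting to all probes reproduces
the unrestricted curve exactly.

### Ontology testing

Gene-level selection is biased toward genes with many probes. The selection
probability is estimated as a lowess fit of the selected indicator on log
probe count, converted to per-gene odds; each category with at least five
universe genes is tested with the Wallenius noncentral hypergeometric
distribution using a single odds parameter, the mean odds of category genes
relative to the rest. With no probe-count variation the odds are 1 and the
test reduces exactly to the central hypergeometric. Cross-tissue agreement
is summarized by ranking categories by p within tissue (average ranks on
ties) and summing ranks.

The Wallenius upper tail is evaluated from the integral representation of
the probability mass, computed in log space after substituting
$t = e^{-v}$ and integrating around the interior maximum of the exponent;
this keeps the computation accurate for universes of tens of thousands of
genes, where the binomial coefficients alone overflow. The test suite checks
it against exhaustive enumeration and an exact sequential-urn dynamic
program, including biased odds.

## The synthetic-data generator

The generator emulates the structure the pipeline must recover:

$$\beta_{ij} = \mathrm{logistic}\!\big(\mathrm{logit}(\textstyle\sum_k w_{ik} r_{kj})
 + \textstyle\sum_l f_{il}\lambda_{lj} + \mathrm{sex}_i s_j + \mathrm{dx}_i\,\delta_j + \epsilon_{ij}\big)$$

- **Cell mixtures**: Dirichlet mixing around cord-blood-like means
  (granulocyte 0.43, CD4 0.19, CD8 0.13, B 0.11, nRBC 0.10, monocyte 0.08,
  NK 0.01; concentration 60), over bimodal 450k-like reference profiles.
- **Latent factors**: factor 1 tracks the batch label; loadings hit 30% of
  probes. The `confounding` parameter mixes the (standardized) ASD indicator
  into each factor score; at the default 0 factors are outcome-independent
  and the generator satisfies its null contract (uniform two-group
  p-values). Recovery simulations for the lambda rule plant `confounding =
  0.3` with loading sd 0.6, chosen so the unadjusted model shows clear
  inflation (λ ≈ 2–8) that the estimated surrogate variables can actually
  remove — at much stronger confounding the outcome-protected weighting can
  no longer absorb the shared component, a real limitation of
  outcome-protected latent-factor methods, not of this implementation.
- **Diagnosis effect**: spiked into a `spike_fraction` of CpGs annotated to
  a designated risk-gene set, on the logit scale, calibrated so the induced
  beta-scale difference at β = 0.5 equals `delta` (default 0.05); effects at
  extreme baselines are correspondingly attenuated, so recovery checks read
  the effect at mid-methylation CpGs. Signs are 70% positive, echoing the
  hypermethylation excess reported in cord blood.
- **Sex**: dedicated chrX (2%) and chrY (0.5%) probe blocks with
  sex-dimorphic levels, so the QC sex check is exercisable end to end.
- **Noise and failures**: logit-normal noise (sd 0.15) and a 0.1% detection
  failure rate; outcome prevalence 22% ASD / 43% nonTD / 35% TD.
- **Annotation**: region classes at realistic array proportions (31%
  island, 23% shore, 10% shelf, 36% open sea), 20% enhancer flags, ~80% of
  probes annotated to synthetic genes (~1 gene per 8 probes, 10% of probes
  carrying two symbols).

What the generator does *not* emulate: Infinium I/II probe-chemistry
differences, spatial/array-position artifacts, genomic correlation between
neighboring CpGs, population structure, or realistic gene lengths and GO
topologies. Passing tests therefore demonstrate internal statistical
correctness and recovery under the stated generative model, not performance
on real 450k data.

## Numerical choices and degenerate inputs

- Null calibration of site-wise tests is assessed on autosomal probes with
  cell-composition adjustment: mixing variation is genuine latent structure,
  and unadjusted tests on a single realization are inflated by chance
  correlation between mixing weights and the outcome — precisely the
  phenomenon the adjustment stages exist to remove.
- `beta_to_m` uses offset 0.01 by default and refuses offset 0 when betas
  touch 0 or 1.
- The NNLS sum constraint uses a penalty weight of $10^4 \times \max|R|$;
  row sums can exceed 1 by at most ~$10^{-6}$.
- Constant probes are dropped (with a warning) before SV estimation;
  degenerate strata, single-level covariates, and constant replicate pairs
  yield missing values rather than errors.
- Permutation p-values use the add-one estimator and never reach zero.
- All stochastic steps (generator, permutation controls, CDF test) take
  explicit seeds; the pipeline log records seed, package version and
  filtering counts, and rerunning a configuration reproduces outputs
  byte-for-byte.

## Problem sizes used by the tests

The test suite and acceptance script run generator sizes of 10,000 CpGs ×
120 samples for calibration and power checks, 8,000 × 120 for the
surrogate-variable selection study (10 seeds), and 1,000–4,000 CpGs for unit
tests — sizes chosen so each property suite completes in minutes while
keeping Monte-Carlo error well inside the asserted tolerances.

## Worked example

```{r, eval = FALSE}
sim <- simulate_dataset(n_samples = 120, n_cpgs = 10000,
                        spike_fraction = 0.3, delta = 0.05, seed = 7)
res <- fit_sitewise(sim$beta, sim$sheet)
enr <- enrichment_curve(res, sim$annotation, sim$risk_genes,
                        n_perm = 10, seed = 1)
subset(enr$curve, threshold == 0.05)
```

See the README for the output this produces and how to reproduce the
package's headline numbers with `scripts/acceptance.R`.
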
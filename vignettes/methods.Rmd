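---
title: "Module- and region-based methylation survival analysis: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Module- and region-based methylation survival analysis: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

Single-CpG epigenome-wide association studies of disease outcomes replicate
poorly across cohorts. `methmodsurv` implements two aggregation strategies
that trade single-site resolution for robustness, wired into a two-cohort
(discovery/replication) survival design:

1. **Correlation modules**: unsigned weighted-correlation-network analysis
   groups CpGs into co-methylation modules; each module is summarized by its
   first principal component across samples (the *eigenCpG*), which enters a
   Cox proportional-hazards model. Discovery-cohort PC weights are projected
   onto the replication cohort, and permutation Z statistics quantify module
   preservation.
2. **Genomic regions**: per-CpG Cox EWAS p-values feed an
   autocorrelation-corrected region caller (Stouffer-Liptak-Kechris
   smoothing, contiguous-run detection, Stouffer-Liptak regional p, Sidak
   correction with region-size-scaled effective tests).

Around these sit the supporting analyses a blood-methylation survival study
needs: detection-based QC, control-probe principal components as technical
covariates, reference-based cell-fraction deconvolution, enrichment
statistics (Wallenius gene-set tests, hypergeometric flag/locus overlap,
chromatin-peak relative enrichment), cumulative risk-factor construction
with Baron-Kenny-style Cox mediation, and summary-statistic Mendelian
randomization estimators.

Everything is exercised on synthetic cohorts; no restricted data are needed.

# The synthetic cohort generator

The generator (`generate_annotation()`, `true_module_spec()`,
`generate_cohort()`, `implant_dmr()`) is first-class, tested code: it defines
the statistical structure every downstream claim is tested against.

**Latent-factor M-value model.** Beta values are bounded in [0,1], so the
generator works on the M-value (logit2) scale and maps back through the
logistic transform `beta = 1/(1 + 2^(-m))`. Each CpG has a baseline level
`mu_j ~ N(0, 1.5)`; module members add `loading * factor_k`; everything gets
`N(0, noise_sd)` noise. With the defaults (loading 0.9, factor sd 1, noise
sd 0.9) the first principal component of a module explains about half of the
member variance and member-member correlations sit near 0.5 — the regime in
which module behavior is meaningfully summarized by one eigenvector, with
the rest of the spectrum flat.

**Risk-factor trajectories.** Each risk factor follows a stationary AR(1)
across exams (default `phi = 0.6`, unit marginal variance), so the mean over
past exams carries information beyond the final-exam value. A designated
factor's standardized cumulative mean (exams 1..E-1) is added, scaled by
`exposure_coef`, to the module factors: module activation becomes a partial
record of cumulative exposure, which is the structure behind the
cumulative-vs-current contrasts. Biomarkers are mapped to realistic
original-scale values (log-normal around typical clinical medians; BMI
linear) so that the covariate-preparation conventions (log10 transforms,
a >125 mg/dL fasting-glucose diabetes flag, pack-year reconstruction) have
something real to act on.

**Survival.** Event times are exponential with log-hazard
`sum_k gamma_k z(factor_k)` plus a small age term. Censoring is exponential
and independent given covariates, with the per-sample censoring rate set
proportional to the event rate (`c_s = rate_s * censor_rate/(1 -
censor_rate)`), which makes the event probability exactly `1 - censor_rate`
for every sample regardless of covariate effects — convenient for calibrated
tests and harmless for the methods, which never use this fact.

**Cell-type structure.** Cell fractions are Dirichlet draws around typical
blood proportions (granulocyte-dominated). Mixing module CpGs linearly in
beta space would destroy the module-correlation calibration, so the linear
mixture `beta = fractions %*% reference + noise` is confined to a dedicated
set of signature CpGs disjoint from the modules. Two consequences worth
knowing: the deconvolution tests run on exactly the structure the Houseman
approach assumes, and the signature CpGs form a genuine fourth correlated
block which unsupervised module detection correctly discovers — recovery is
therefore scored against the truth *including* that block.

**Batch.** A two-level batch factor drives the control-probe intensities
(log-scale loadings) and adds a small (0.005) beta shift to a random 20% of
CpGs, giving control-probe PCA a real signal to remove.

**DMR implantation.** `implant_dmr()` adds `effect * u_s` (frailty
`u_s ~ N(0,1)`) to the M-values of a contiguous CpG run and multiplies both
the event and censoring hazards by `exp(effect * u_s)` (implemented as a
time rescaling), coupling region methylation to hazard without changing the
event indicator or marginal event rate. `effect = 0` is exactly the
identity.

**What the generator does not emulate:** probe-type chemistry (Type I/II),
raw intensity artifacts, SNP-under-probe contamination, genomic waves,
family structure, age-dependent methylation drift, and non-exponential
baseline hazards. Passing tests demonstrate the machinery is correct and
calibrated under the stated model; they do not certify performance on real
arrays, where QC lists, normalization and richer confounding matter.

# Module detection

`detect_modules()` follows the blockwise recipe: k-means pre-clustering of
standardized CpG profiles on a random subject subsample (default 100
subjects; centers `2 * ceiling(n_cpgs / block_size)`, block cap 20,000
CpGs), then per block Pearson correlation, unsigned adjacency `|r|^power`
(default power 8, chosen to balance approximate scale-free topology against
connectivity — `pick_soft_threshold()` reports the diagnostics), topological
overlap, average-linkage clustering of `1 - TOM`, and a static branch cut.
Unsigned networks are used because the biological reading of a methylation
increase versus decrease is far less clear than for transcripts.

Numerical choices that were genuinely open:

* **Static cut height, default 0.999.** Under the generator's own
  calibration (member correlation ~0.5, so adjacency `0.5^8 ≈ 0.004`),
  within-module `1 - TOM` dissimilarities sit near 0.996 while noise pairs
  sit within about 1e-5 of 1. A cut at 0.995 would therefore refuse to merge
  true module members; 0.999 separates the two populations with a wide
  margin on both sides. The parameter is exposed for data with different
  correlation strength.
* **Merging** at eigenCpG correlation > 0.75 (the conventional 0.25 merge
  height), iteratively, largest pair first.
* **Scale-free fit bins.** The `log10(freq(k)) ~ log10(k)` regression uses
  equal-width connectivity bins; equal-count bins would make the response
  constant by construction.
* Modules are relabeled by descending size and given conventional color
  aliases, with grey = unassigned.

EigenCpGs (`compute_eigencpgs()`) standardize member CpGs and take the first
right singular vector; scores are oriented to correlate nonnegatively with
the mean standardized member profile, making signs reproducible.
Projection (`project_eigencpgs()`) standardizes the *new* cohort with its
own means and sds — the weights, not the scaling, carry the discovery
information — dropping missing CpGs and renormalizing weights to unit norm,
with a 90% minimum-overlap guard (arrays shared across cohorts overlap
almost completely, so falling below 90% signals a real mismatch).

Preservation (`module_preservation()`) compares a module's mean within-module
adjacency (density) and the cross-cohort correlation of intramodular
connectivity vectors (connectivity) against `n_perm` size-matched random
sets of unassigned CpGs; `Z_summary` is the mean of the two permutation Zs,
with 10 the conventional strong-preservation threshold. When a null
statistic is numerically degenerate (e.g. connectivity when the test data
*are* the discovery data, where all correlations are exactly 1), its Z is
defined as 0 rather than NaN.

# Survival modeling

`fit_cox()` wraps the survival package's partial-likelihood Newton-Raphson
engine (Efron tie handling by default, Breslow available) behind a stable
interface that reports coefficients, SEs, Wald z/p, iterations, and a
`converged` flag; a monotone likelihood (perfect separation) flags rather
than fails. Tests check the fitter against an independent grid-search
maximizer of the explicitly written partial likelihood on small instances,
plus type-I error calibration and coefficient recovery at scale.
`ph_check()` runs the scaled-Schoenfeld score test against event-time rank.

Model tiers mirror the study design: *minimal* models adjust for estimated
cell fractions plus technical covariates (batch and control-probe PCs);
*full* models add age, BMI, smoking status, pack-years, and sex/race where
present. All six cell fractions are compositional, so models include five
(granulocytes dropped) in every tier. The per-CpG EWAS (`ewas_scan()`)
applies a per-CpG IQR outlier mask (`[Q1 - 3 IQR, Q3 + 3 IQR]`, type-7
quantiles) before fitting raw beta values (no standardization, so
coefficients are per unit beta), reports non-converged CpGs as missing p,
and summarizes confounding control with the median-based genomic inflation
factor.

The cell-type interaction scan fits a single Cox model with the module
score, five fractions, and five score-by-fraction interactions,
highlighting the monocyte term — the interaction-based reading of cell-type
specificity.

# Region calling

`call_dmrs()` composes the comb-p style stages with the study's settings as
defaults: distance-binned ACF of probit-transformed p-values (bins of 50 bp
out to 1 kb; bins with under 10 pairs inherit the nearest informative
estimate; estimates are clipped to [0, 1) when used as covariances so the
combined-z denominator stays positive), Stouffer-Liptak-Kechris per-site
adjustment over 1 kb windows, contiguous-run detection (adjusted p < 0.1,
gaps ≤ 500 bp, at least 2 probes), an ACF re-estimated out to the maximum
region span, Stouffer-Liptak regional p on the raw member p-values, and
Sidak correction with effective tests = loci tested / loci in region (a
base-pair variant is available as `sidak_basis = "bases"`). p-values are
clipped to [1e-300, 1 - 1e-16] before the probit transform. Intervals are
0-based half-open internally with a 1-based inclusive location string in
reports. Cross-cohort replication joins regions by ≥1 bp overlap with a
Bonferroni threshold of 0.05 over the number of discovery regions.

# Enrichment statistics

Flag and locus-category overlap use the exact hypergeometric distribution
against the QC-surviving background; clock/Polycomb tests read the upper
tail (the direction in which such enrichments are reported), locus
categories the two-tailed minimum-likelihood p. Gene-set tests correct for
the CpG-count-per-gene selection bias with Wallenius' noncentral
hypergeometric distribution (odds weight = mean CpG count inside the set
over outside), evaluated by the exact sequential-draw recursion — O(n²),
no quadrature error, and identically the central distribution at w = 1.
Cell-type specificity uses the ratio of in-peak fractions
(module vs background) reported as log2 relative enrichment, with
zero-overlap cells flagged rather than infinite; peak membership accepts
either annotation flag columns or BED intervals (0-based half-open).

# Risk factors, mediation, and MR

Cumulative exposure is the mean of transformed risk-factor values over the
exams preceding the methylation exam, requiring at least 3 past values
(the study pooled seven exams without stating a missingness rule; 3 is a
conservative floor, configurable). Adjusted module-risk factor models
standardize both the eigenCpG and the factor so betas are comparable across
factors and modules. Mediation fits the three Cox models (exposure only,
mediator only, both) on the identical complete-case sample and reports
coefficient/p attenuation descriptively; Cox coefficients are
non-collapsible, so attenuation fractions are read as evidence ordering,
not an effect decomposition. MR estimators (Wald ratio, fixed-effect IVW,
MR-Egger WLS with intercept, weighted median with seeded parametric
bootstrap SE) operate on per-SNP summary statistics; the weighted-mode
estimator and any database lookups are out of scope.

# Problem sizes and reproducibility

The test suite and the acceptance script run the methods at deliberately
chosen scales: module recovery and preservation on 5,000 CpGs x 800
samples; DMR recovery on 5,000 CpGs x 1,000 samples with a 5-CpG implant
(effect 1.0 on the M scale) across seeded replicates; Cox calibration at
n = 2,000 with 500 null simulations; smaller scenes (≤ 1,200 CpGs) for the
pipeline integration test. These sizes make every property measurable with
comfortable statistical margins while keeping a full run in minutes on one
core. All randomness flows through explicit integer seeds (`with_seed`
restores the caller's RNG state), and the end-to-end pipeline writes a
manifest of stage checksums: the same seed reproduces every output
bit-for-bit.

# Known limitations

* The pipeline starts at normalized beta values; IDAT parsing, Noob/BMIQ
  normalization and sex-prediction QC are out of scope, and exclusion lists
  are consumed as plain inputs.
* The deconvolution renormalizes the simplex-constrained solution to sum
  exactly to 1 (the classical constrained projection leaves sums ≤ 1).
* Static-cut module detection is simpler than dynamic hybrid tree cutting;
  on real data with shallow module structure the cut height may need tuning.
* Preservation connectivity Zs are uninformative when module loadings are
  homogeneous (as in the generator's defaults), because intramodular
  connectivity has no hub structure to preserve; density carries the signal.
* Mediation is descriptive Baron-Kenny with Cox outcomes; no
  indirect-effect confidence intervals are computed.
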
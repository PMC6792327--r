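# methmodsurv

Module- and region-based DNA methylation survival analysis for incident
disease, with a synthetic-cohort generator that makes the whole pipeline
testable without restricted data.

## The problem and who this is for

Single-CpG epigenome-wide association studies (EWAS) of incident disease
replicate poorly across cohorts. This package implements, for epigenetic
epidemiologists working with 450K-style blood methylation arrays and
time-to-event outcomes, the two standard aggregation strategies that trade
single-site resolution for robustness:

* **Co-methylation modules** (WGCNA-style): unsigned weighted correlation
  networks on CpGs (`adjacency a_ij = |cor(x_i, x_j)|^β`, default β = 8),
  topological-overlap clustering into modules, per-module **eigenCpGs**
  (first principal component scores), Cox proportional-hazards scans of
  eigenCpGs against incident events, cross-cohort projection of the PC
  weights, and permutation **Z_summary** preservation statistics (density +
  connectivity, strong preservation at Z > 10).
* **Differentially methylated regions** (comb-p style): per-CpG Cox EWAS
  p-values, a distance-binned autocorrelation function (50 bp bins to
  1 kb), Stouffer-Liptak-Kechris per-site adjustment
  (`z_c = Σ z_j / sqrt(k + 2 Σ σ(d_jl))`), contiguous-region calling
  (adjusted p < 0.1, gaps ≤ 500 bp), Stouffer-Liptak regional p-values, and
  Sidak correction with effective tests = loci tested / loci in region.

Supporting stages: detection-p QC (strict >10% undetected rules),
control-probe PCA technical covariates (k = 7), Houseman-style
cell-fraction deconvolution, per-CpG IQR outlier masking
(`[Q1 − 3·IQR, Q3 + 3·IQR]`), genomic inflation λ, BH FDR, Wallenius
noncentral hypergeometric gene-set enrichment (CpG-count bias correction),
hypergeometric clock/locus overlap tests, chromatin-peak log2 relative
enrichment, cumulative risk-factor construction with Baron-Kenny Cox
mediation, and two-sample MR estimators (Wald ratio, IVW, MR-Egger,
weighted median).

## Worked example

Simulate a discovery cohort with three implanted modules (the first
carrying a hazard of 0.3 log-HR per SD of module activation), detect
modules, and scan them against incident events:

```r
library(methmodsurv)

ann    <- generate_annotation(n_cpgs = 5000, n_chroms = 2, seed = 1)
spec   <- default_module_spec(5000, sizes = c(200, 150, 100), seed = 2,
                              hazard_coef = c(0.3, 0, 0))
cohort <- generate_cohort(spec, ann, n_samples = 800, seed = 3)

mods <- detect_modules(cohort$beta, network_params(), seed = 4)
sapply(mods$modules, length)
#> turquoise      blue     brown    yellow
#>       200       150        97        60

eig <- compute_eigencpgs(cohort$beta, mods)
round(sapply(eig$eigenvectors, function(e) e$variance_explained), 2)
#> turquoise      blue     brown    yellow
#>      0.48      0.51      0.49      0.37
```

The three implanted modules are recovered essentially exactly (the fourth,
`yellow`, is the generator's cell-type signature block — a genuine
correlated structure), and each implanted module's first PC explains about
half its variance, the regime the generator defaults are calibrated to.
The Cox scan then ranks modules by evidence:

```r
cf   <- estimate_cell_fractions(cohort$beta, cohort$reference)
pcs  <- control_probe_pca(cohort$control_probes, k = 7)
scan <- module_cox_scan(eig$scores, cohort$phenotypes, "minimal",
                        cell_fractions = cf, control_pcs = pcs)
scan[, c("module", "coef", "p", "q", "flag")]
#>      module         coef            p            q  flag
#> 1 turquoise  0.029441334 9.639148e-08 3.855659e-07  TRUE
#> 2      blue  0.005490995 3.503646e-01 4.671528e-01 FALSE
#> 3     brown  0.007511452 2.991920e-01 4.671528e-01 FALSE
#> 4    yellow -0.132337859 7.460926e-01 7.460926e-01 FALSE
```

Only the hazardous module is flagged at FDR < 0.2 (coefficients are per
unit eigenCpG score, not per SD); the null modules are not.
`run_pipeline()` chains the whole
two-cohort design (QC → modules → projection/preservation → EWAS → DMRs →
enrichment → mediation) from a single seeded YAML-style config and writes
per-stage TSVs plus a checksum manifest.

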
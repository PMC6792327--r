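test_that("sample QC applies the strictly-more-than-10% rule", {
  dp <- matrix(0, 4, 100, dimnames = list(paste0("s", 1:4), paste0("cg", 1:100)))
  dp["s2", 1:11] <- 1e-10   # 11% undetected -> removed
  dp["s3", 1:10] <- 1e-10   # exactly 10% -> retained
  expect_identical(sample_qc(dp), c("s1", "s3", "s4"))
  expect_error(sample_qc(matrix(numeric(0), 0, 0)), "empty")
})

test_that("probe QC removes undetected, sex-chromosome and listed probes", {
  ann <- data.frame(cpg_id = paste0("cg", 1:10),
                    chrom = c(rep("chr1", 8), "chrX", "chrY"),
                    pos = 1:10)
  dp <- matrix(0, 10, 10, dimnames = list(NULL, ann$cpg_id))
  dp[1:2, "cg1"] <- 1e-5  # 20% of samples undetected -> removed
  dp[1, "cg2"] <- 1e-5    # exactly 10% -> retained
  expect_warning(
    kept <- probe_qc(dp, ann, exclusion_lists = list(snp = c("cg3", "cg99"))),
    "absent")
  expect_identical(kept, paste0("cg", c(2, 4:8)))
  # idempotence: re-running on the retained set changes nothing
  kept2 <- probe_qc(dp[, kept], ann[ann$cpg_id %in% kept, ])
  expect_identical(kept2, kept)
})

test_that("IQR outlier mask matches its closed form", {
  # values with Q1 = 2, Q3 = 4 -> bounds [-4, 10]; 11 is masked out
  v <- c(2, 2, 2, 3, 4, 4, 4, 11)
  q <- quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
  expect_equal(q, c(2, 4))
  mask <- iqr_outlier_mask(v)
  expect_identical(mask, c(rep(TRUE, 7), FALSE))
  expect_true(all(iqr_outlier_mask(rep(0.5, 10))))  # zero IQR: keep all
  expect_error(iqr_outlier_mask(c(1, 2, NA, NA)), "at least 4")
  # standard-normal tail: expected masked fraction well below 0.1%
  set.seed(42)
  x <- rnorm(1000)
  expect_lt(mean(!iqr_outlier_mask(x)), 0.001)
})

test_that("control-probe PCA isolates a rank-1 batch factor", {
  set.seed(7)
  n <- 40
  batch <- rnorm(n)
  loading <- runif(30, 0.5, 2)
  x <- 2^(outer(batch, loading) + 10)
  expect_warning(pcs <- control_probe_pca(x, k = 7), "rank")
  expect_gt(pcs$var_frac[1], 0.999)
  expect_gt(abs(cor(pcs$scores[, 1], batch)), 0.999)
})

test_that("control-probe PCA scores are orthogonal, sign-fixed and equivariant", {
  set.seed(8)
  x <- matrix(2^rnorm(50 * 20, 10), 50, 20)
  pcs <- control_probe_pca(x, k = 7)
  expect_equal(ncol(pcs$scores), 7)
  g <- crossprod(scale(pcs$scores, scale = FALSE))
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
  expect_true(all(diff(pcs$var_frac) <= 1e-12))
  expect_lte(sum(pcs$var_frac), 1 + 1e-12)
  # sign convention: largest-magnitude loading entry positive
  for (j in 1:7) {
    v <- pcs$rotation[, j]
    expect_gt(v[which.max(abs(v))], 0)
  }
  # permutation equivariance
  perm <- sample(50)
  pcs_p <- control_probe_pca(x[perm, ], k = 7)
  expect_equal(pcs_p$scores, pcs$scores[perm, ], tolerance = 1e-8)
  # invariance (up to sign fix) to per-probe affine rescaling of log intensity
  scl <- runif(20, 0.5, 3)
  x2 <- 2^(sweep(log2(x), 2, scl, `*`) + rep(1, 50) %o% runif(20))
  pcs_a <- control_probe_pca(x2, k = 7)
  for (j in 1:3) {
    expect_gt(abs(cor(pcs_a$scores[, j], pcs$scores[, j])), 1 - 1e-6)
  }
})

test_that("cell deconvolution recovers exact and mixed reference profiles", {
  set.seed(9)
  ref <- matrix(runif(360, 0.05, 0.95), 60, 6,
                dimnames = list(paste0("cg", 1:60),
                                c("CD4T", "CD8T", "B", "NK", "Mono", "Gran")))
  # beta equal to reference column j -> unit vector e_j
  beta <- t(ref[, c(2, 5)])
  rownames(beta) <- c("a", "b")
  cf <- estimate_cell_fractions(beta, ref)
  expect_equal(unname(cf$fractions["a", ]), c(0, 1, 0, 0, 0, 0), tolerance = 1e-6)
  expect_equal(unname(cf$fractions["b", ]), c(0, 0, 0, 0, 1, 0), tolerance = 1e-6)
  # 50/50 mixture of two columns
  mix <- matrix(0.5 * ref[, 1] + 0.5 * ref[, 2], 1,
                dimnames = list("m", rownames(ref)))
  cfm <- estimate_cell_fractions(mix, ref)
  expect_equal(unname(cfm$fractions[1, ]), c(0.5, 0.5, 0, 0, 0, 0),
               tolerance = 1e-6)
  # rank-deficient reference is an error
  bad <- ref
  bad[, 2] <- bad[, 1]
  expect_error(estimate_cell_fractions(mix, bad), "rank-deficient")
})

test_that("deconvolution of noisy Dirichlet mixtures has small error and valid simplex", {
  sc <- small_scene()
  co <- sc$cohort
  cf <- estimate_cell_fractions(co$beta, co$reference)
  expect_true(all(cf$fractions >= 0))
  expect_equal(unname(rowSums(cf$fractions)), rep(1, nrow(cf$fractions)),
               tolerance = 1e-9)
  expect_lt(mean(abs(cf$fractions - co$true_fractions)), 0.05)
})

test_that("covariate preparation transforms, imputes and derives flags", {
  ph <- data.frame(
    sample_id = paste0("s", 1:5), time = 1:5, event = c(1, 0, 1, 0, 1),
    age = 60:64, bmi = c(25, NA, 30, 28, 27),
    smoking_status = c(0, 0, NA, 1, 0),
    pack_years = c(0, 0, NA, NA, 0),
    years_smoking = c(0, 0, 0, 20, 0), packs_per_day = c(0, 0, 0, 0.5, 0),
    bp_med = c(0, 0, 0, 1, 0), lipid_med = 0, diabetes_med = c(0, 0, 0, 0, 1),
    glu = c(100, 126, 90, 95, 100), hscrp = c(1, 2, 3, 4, 5),
    chol = 200, ldl = 120, hdl = 50, tg = 100, sbp = 130)
  out <- prepare_covariates(ph)
  expect_equal(out$hscrp[1], 0)                       # log10(1) = 0
  expect_equal(out$glu, log10(ph$glu))
  expect_equal(out$bmi[2], median(c(25, 30, 28, 27))) # median imputation
  expect_equal(out$smoking_status[3], 0)              # median of mostly 0
  expect_equal(out$pack_years[4], 10)                 # 20y x 0.5 packs/day
  expect_equal(out$pack_years[3], 0)
  # diabetes: glucose > 125 mg/dL (strict) OR medication
  expect_equal(out$diabetes, c(0, 1, 0, 0, 1))
  ph_bad <- ph
  ph_bad$tg[2] <- -1
  expect_error(prepare_covariates(ph_bad), "tg.*s2|s2.*tg")
  ph_na <- ph
  ph_na$hdl[1] <- NA
  expect_error(prepare_covariates(ph_na), "hdl")
})
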
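test_that("annotation generation validates inputs and is deterministic", {
  expect_error(generate_annotation(0), "empty annotation")
  expect_error(generate_annotation(100, clock_size = 353), "clock larger than array")
  a1 <- generate_annotation(500, n_chroms = 2, clock_size = 40, seed = 1)
  a2 <- generate_annotation(500, n_chroms = 2, clock_size = 40, seed = 1)
  expect_identical(a1, a2)
  expect_equal(sum(a1$horvath), 40)
  expect_equal(sum(a1$hannum), 40)
  # positions strictly increasing within chromosome, sorted on disk order
  for (ch in unique(a1$chrom)) {
    expect_true(all(diff(a1$pos[a1$chrom == ch]) > 0))
  }
  expect_false(is.unsorted(order(a1$chrom, a1$pos)))
  # gap mixture: both short (<500) and long (>1kb) gaps present
  gaps <- diff(a1$pos[a1$chrom == "chr1"])
  expect_true(any(gaps < 500) && any(gaps > 1000))
  expect_true(all(a1$gene_group %in% c("TSS1500", "TSS200", "5UTR", "1stExon",
                                       "Body", "3UTR", "intergenic")))
  expect_true(all(a1$island_relation %in% c("Island", "N_Shore", "S_Shore",
                                            "N_Shelf", "S_Shelf", "OpenSea")))
})

test_that("peak flag density matches its target within binomial bounds", {
  ann <- generate_annotation(10000, peak_density = 0.25, seed = 7)
  frac <- mean(ann$peak_Mono_DNase)
  half_width <- qnorm(0.995) * sqrt(0.25 * 0.75 / 10000)
  expect_gt(frac, 0.25 - half_width)
  expect_lt(frac, 0.25 + half_width)
})

test_that("cohort event fraction is calibrated and generation is reproducible", {
  ann <- generate_annotation(300, clock_size = 30, seed = 2)
  spec <- default_module_spec(300, sizes = c(40), seed = 3, hazard_coef = 0)
  co <- generate_cohort(spec, ann, n_samples = 1000, censor_rate = 0.5, seed = 4)
  expect_true(all(co$beta >= 0 & co$beta <= 1))
  expect_true(all(co$phenotypes$time > 0))
  expect_true(all(co$phenotypes$event %in% c(0, 1)))
  expect_equal(range(rowSums(co$true_fractions)), c(1, 1), tolerance = 1e-9)
  half_width <- qnorm(0.995) * sqrt(0.25 / 1000)
  expect_lt(abs(mean(co$phenotypes$event) - 0.5), half_width)
  co2 <- generate_cohort(spec, ann, n_samples = 1000, censor_rate = 0.5, seed = 4)
  expect_identical(co, co2)
  expect_error(
    generate_cohort(true_module_spec(list(290:305)), ann, 10),
    "exceeds")
})

test_that("member CpG M-values approach perfect correlation as noise vanishes", {
  ann <- generate_annotation(100, clock_size = 20, seed = 5)
  spec <- true_module_spec(list(1:20), loadings = 1, noise_sd = 1e-4)
  co <- generate_cohort(spec, ann, n_samples = 100, seed = 6)
  m <- logit2(co$beta[, 1:20])
  cc <- cor(m)
  expect_true(all(abs(cc[upper.tri(cc)]) > 0.99))
})

test_that("beta/M mapping is a bijection on (0,1)", {
  set.seed(11)
  m <- rnorm(1000, sd = 3)
  expect_equal(logit2(ilogit2(m)), m, tolerance = 1e-12)
  b <- runif(1000)
  expect_equal(ilogit2(logit2(b)), b, tolerance = 1e-12)
})

test_that("cumulative exposure correlates with the driven factor more than the current value", {
  # the molecular-recorder structure: with exposure_coef > 0 and phi <= 0.7,
  # cumulative (pre-final-exam mean) exposure tracks the module factor better
  # than the final-exam value alone
  ann <- generate_annotation(120, clock_size = 20, seed = 8)
  spec <- true_module_spec(list(1:40), exposure_coef = 0.5)
  co <- generate_cohort(spec, ann, n_samples = 1000, seed = 9, phi = 0.6)
  fac <- co$truth$factors[, 1]
  cum <- cumulative_exposure(co$exposures, "bmi")[co$phenotypes$sample_id]
  cur <- co$phenotypes$bmi
  expect_gt(cor(cum, fac), 0)
  expect_gt(abs(cor(cum, fac)), abs(cor(cur, fac)))
})

test_that("implant_dmr validates regions and is the identity at zero effect", {
  sc <- small_scene()
  ann <- sc$ann
  run <- NULL
  for (i in seq_len(nrow(ann) - 4)) {
    w <- i:(i + 4)
    if (length(unique(ann$chrom[w])) == 1 && all(diff(ann$pos[w]) < 500)) {
      run <- w
      break
    }
  }
  expect_false(is.null(run))
  expect_identical(implant_dmr(sc$cohort, ann, run, effect = 0), sc$cohort)
  co2 <- implant_dmr(sc$cohort, ann, run, effect = 1, seed = 5)
  untouched <- setdiff(seq_len(ncol(sc$cohort$beta)), run)
  expect_identical(co2$beta[, untouched], sc$cohort$beta[, untouched])
  expect_false(identical(co2$beta[, run], sc$cohort$beta[, run]))
  # a region with an internal gap >= 500 bp is rejected
  gap_i <- which(ann$chrom[-nrow(ann)] == ann$chrom[-1] & diff(ann$pos) >= 600)[1]
  expect_error(implant_dmr(sc$cohort, ann, c(gap_i, gap_i + 1), effect = 1),
               "internal gap")
  # spanning chromosomes is rejected
  br <- max(which(ann$chrom == "chr1"))
  expect_error(implant_dmr(sc$cohort, ann, c(br, br + 1), effect = 1),
               "spans chromosomes")
})

test_that("detection p-values exercise the QC threshold", {
  sc <- small_scene()
  dp <- sc$cohort$detection_p
  expect_true(any(dp > 1e-16))
  expect_gt(mean(dp < 1e-16), 0.99)
})

test_that("cohorts round-trip to plain-text files", {
  sc <- small_scene()
  dir <- withr::local_tempdir()
  sets <- generate_gene_sets(sc$ann, n_sets = 4, set_size = 10, seed = 1)
  files <- write_cohort(sc$cohort, sc$ann, dir, gene_sets = sets)
  expect_true(all(file.exists(files)))
  beta_in <- as.matrix(utils::read.table(file.path(dir, "beta.tsv"),
                                         header = TRUE, row.names = 1,
                                         check.names = FALSE))
  expect_equal(t(beta_in), sc$cohort$beta, tolerance = 1e-6,
               ignore_attr = FALSE)
  gmt <- read_gmt(file.path(dir, "gene_sets.gmt"))
  expect_identical(gmt, sets)
  bed <- read_bed(file.path(dir, "Mono.DNase.bed"))
  expect_true(all(bed$end > bed$start))
})
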
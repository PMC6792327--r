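test_that("ACF estimation matches hand-computed correlations", {
  # 6 sites, pairs within 50 bp computed by hand
  z <- c(1.2, 0.7, -0.3, 0.9, 1.8, 0.1)
  p <- 1 - pnorm(z)
  sites <- data.frame(chrom = "chr1",
                      pos = c(100L, 140L, 180L, 1000L, 1040L, 1080L), p = p)
  acf <- suppressWarnings(estimate_acf(sites, max_dist = 100, step = 50,
                                       min_pairs = 2))
  # bin [1,51): pairs (1,2),(2,3),(4,5),(5,6)
  a <- z[c(1, 2, 4, 5)]
  b <- z[c(2, 3, 5, 6)]
  expect_equal(acf$cor[1], cor(a, b), tolerance = 1e-12)
  # bin [51,101): pairs (1,3),(4,6)
  a2 <- z[c(1, 4)]
  b2 <- z[c(3, 6)]
  expect_equal(acf$cor[2], cor(a2, b2), tolerance = 1e-12)
  expect_equal(acf$n_pairs, c(4L, 2L))
})

test_that("ACF of independent p-values is near zero; duplicated tracks give 1", {
  set.seed(71)
  n <- 5000
  pos <- sort(sample.int(2e6, n))
  sites <- data.frame(chrom = "chr1", pos = pos, p = runif(n))
  acf <- estimate_acf(sites)
  ok <- acf$n_pairs >= 10
  expect_true(all(abs(acf$cor[ok]) <= 3 / sqrt(acf$n_pairs[ok])))
  # duplicated p-value track at fixed 40 bp offsets: bin [1,50) estimate -> 1
  p2 <- runif(200)
  dup <- data.frame(chrom = "chr1",
                    pos = as.integer(rbind(seq(1, by = 2000, length.out = 200),
                                           seq(41, by = 2000, length.out = 200))),
                    p = as.vector(rbind(p2, p2)))
  acf2 <- suppressWarnings(estimate_acf(dup))
  expect_equal(acf2$cor[1], 1, tolerance = 1e-12)
  expect_equal(acf2$sigma[1], 1 - 1e-8)
})

test_that("SLK adjustment reproduces Stouffer closed forms", {
  # isolated site with zero ACF: identity
  iso <- data.frame(chrom = "chr1", pos = c(100L, 5000L), p = c(0.05, 0.2))
  expect_equal(slk_adjust(iso, make_acf(0)), c(0.05, 0.2), tolerance = 1e-12)
  # two sites 40 bp apart, ACF 1: perfectly dependent pair, p unchanged
  pair <- data.frame(chrom = "chr1", pos = c(100L, 140L), p = c(0.05, 0.05))
  expect_equal(slk_adjust(pair, make_acf(1)), c(0.05, 0.05), tolerance = 1e-6)
  # same pair, ACF 0: z_c = 2 * 1.6449 / sqrt(2) -> p = 0.0100
  adj <- slk_adjust(pair, make_acf(0))
  expect_equal(adj, rep(1 - pnorm(2 * qnorm(0.95) / sqrt(2)), 2),
               tolerance = 1e-12)
  expect_equal(round(adj[1], 4), 0.0100)
})

test_that("region finding applies the threshold/gap/min-probe rules", {
  sites <- data.frame(chrom = "chr1", pos = c(100L, 200L, 800L, 900L),
                      p = rep(0.5, 4))
  regions <- find_regions(sites, c(0.01, 0.05, 0.02, 0.03))
  expect_equal(nrow(regions), 2)  # 600 bp gap splits the run
  expect_equal(regions$start, c(99L, 799L))
  expect_equal(regions$end, c(200L, 900L))
  expect_equal(regions$n_probes, c(2L, 2L))
  expect_equal(nrow(find_regions(sites, rep(0.5, 4))), 0)
  # single sub-threshold site flanked by gaps is discarded (min_probes 2)
  expect_equal(nrow(find_regions(sites, c(0.01, 0.5, 0.5, 0.5))), 0)
})

test_that("regional Stouffer-Liptak p matches hand arithmetic", {
  # single member: identity
  expect_equal(region_p(data.frame(pos = 100L, p = 0.037), make_acf(0)), 0.037)
  # 4 members, pairwise ACF 1: z_c = mean(z); all p = 0.05 -> 0.05
  m4 <- data.frame(pos = c(100L, 120L, 140L, 160L), p = rep(0.05, 4))
  expect_equal(region_p(m4, make_acf(1, n_bins = 2)), 0.05, tolerance = 1e-6)
  # 3 members, p = (0.01, 0.02, 0.05), all pairwise sigma = 0.5:
  # z_c = 6.0249 / sqrt(6) = 2.4597 -> p = 0.00695
  m3 <- data.frame(pos = c(100L, 140L, 180L), p = c(0.01, 0.02, 0.05))
  rp <- region_p(m3, make_acf(0.5, n_bins = 2))
  z_hand <- (qnorm(0.99) + qnorm(0.98) + qnorm(0.95)) / sqrt(3 + 2 * 1.5)
  expect_equal(rp, 1 - pnorm(z_hand), tolerance = 1e-12)
  expect_equal(round(rp, 5), 0.00695)
  # invariant to member ordering
  expect_equal(region_p(m3[c(3, 1, 2), ], make_acf(0.5, n_bins = 2)), rp,
               tolerance = 1e-12)
})

test_that("Sidak correction follows the effective-test formula", {
  expect_equal(sidak_correct(0, 1000, 10), 0)
  expect_equal(sidak_correct(1, 1000, 10), 1)
  expect_equal(sidak_correct(0.001, 1000, 10), 1 - 0.999^100, tolerance = 1e-12)
  expect_equal(round(sidak_correct(0.001, 1000, 10), 5), 0.09521)
  expect_equal(sidak_correct(0.037, 500, 500), 0.037, tolerance = 1e-15)
  # monotone increasing in the number of effective tests
  m_vals <- sapply(c(1, 2, 5, 10, 50), function(nr) sidak_correct(0.01, 100, 100 / nr))
  expect_true(all(diff(m_vals) > 0))
  expect_error(sidak_correct(1.2, 10, 5), "outside")
})

test_that("end-to-end DMR calling recovers an implanted region with bookkeeping", {
  sc <- small_scene()
  ann <- sc$ann
  run <- NULL
  for (i in seq_len(nrow(ann) - 2)) {
    w <- i:(i + 2)
    if (length(unique(ann$chrom[w])) == 1 && all(diff(ann$pos[w]) < 500)) {
      run <- w
      break
    }
  }
  co <- implant_dmr(sc$cohort, ann, run, effect = 1.5, seed = 9)
  ew <- ewas_scan(co$beta, co$phenotypes, covariate_tier = "minimal",
                  annotation = ann)
  dmrs <- call_dmrs(ew)
  expect_true(nrow(dmrs) >= 1)
  hit <- dmrs[dmrs$chrom == ann$chrom[run[1]] &
                dmrs$start < ann$pos[run[3]] & dmrs$end >= ann$pos[run[1]], ]
  expect_true(nrow(hit) >= 1)
  expect_gte(hit$n_probes[1], 3)
  implanted_ids <- ann$cpg_id[run]
  expect_true(all(implanted_ids %in% strsplit(hit$cpgs[1], ",")[[1]]))
  expect_true(all(dmrs$sidak_p >= 0 & dmrs$sidak_p <= 1))
  expect_true(all(dmrs$start < dmrs$end))
  expect_false(is.unsorted(dmrs$sidak_p))
  expect_equal(dmrs$n_pos + dmrs$n_neg, dmrs$n_probes)
  expect_error(call_dmrs(ew$results[1:50, ]), "100 sites")
})
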
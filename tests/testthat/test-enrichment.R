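# Exhaustive enumeration oracle for hypergeometric overlap on a small
# universe: enumerate all C(N, n) query draws.
enumerate_overlap <- function(N, K, n) {
  combs <- utils::combn(N, n)
  k_obs <- colSums(combs <= K)  # items 1..K are "annotated"
  tabulate(k_obs + 1L, nbins = n + 1L) / ncol(combs)
}

test_that("hypergeometric tails match exhaustive enumeration for N <= 12", {
  for (N in c(8, 10, 12)) {
    for (K in c(3, 5)) {
      for (n in c(2, 4)) {
        pmf <- enumerate_overlap(N, K, n)
        for (k in max(0, n + K - N):min(n, K)) {
          h <- methmodsurv:::hypergeom_counts(k, n, K, N)
          expect_equal(h$p_upper, sum(pmf[(k + 1):(n + 1)]), tolerance = 1e-12)
          expect_equal(h$p_lower, sum(pmf[1:(k + 1)]), tolerance = 1e-12)
          two <- sum(pmf[pmf <= pmf[k + 1] * (1 + 1e-7)])
          expect_equal(h$p_two, min(1, two), tolerance = 1e-12)
          # tail identity: upper + lower - point mass = 1
          expect_equal(h$p_upper + h$p_lower - pmf[k + 1], 1, tolerance = 1e-12)
        }
      }
    }
  }
  # N=10, K=5, n=4, k=4 -> 5/210
  h <- methmodsurv:::hypergeom_counts(4, 4, 5, 10)
  expect_equal(h$p_upper, 5 / 210, tolerance = 1e-12)
})

test_that("hypergeom_overlap handles sets and degenerate cases", {
  bg <- paste0("cg", 1:40)
  expect_error(hypergeom_overlap("x", bg[1:5], bg), "subset")
  expect_error(hypergeom_overlap(bg[1:5], bg[1:5], character(0)), "empty")
  h <- hypergeom_overlap(bg, bg[1:10], bg)  # query = background
  expect_equal(h$k, h$K)
  expect_equal(h$p_two, 1)
})

test_that("Wallenius reduces to the central distribution at w = 1", {
  expect_equal(dwallenius(50, 1950, 100, 1), dhyper(0:100, 50, 1950, 100),
               tolerance = 1e-10)
  expect_equal(dwallenius(500, 1500, 120, 1), dhyper(0:120, 500, 1500, 120),
               tolerance = 1e-10)
  expect_equal(pwallenius_upper(7, 50, 1950, 100, 1),
               phyper(6, 50, 1950, 100, lower.tail = FALSE), tolerance = 1e-10)
})

test_that("Wallenius pmf matches enumeration of biased sequential draws", {
  # exhaustive recursion over ordered draws from a 9-gene universe (m1 = 4)
  enum_wallenius <- function(m1, m2, n, w) {
    pmf <- numeric(n + 1)
    recurse <- function(x, j, prob) {
      if (j == n) {
        pmf[x + 1] <<- pmf[x + 1] + prob
        return()
      }
      sw <- w * (m1 - x)
      fw <- m2 - (j - x)
      if (sw > 0) recurse(x + 1, j + 1, prob * sw / (sw + fw))
      if (fw > 0) recurse(x, j + 1, prob * fw / (sw + fw))
    }
    recurse(0, 0, 1)
    pmf
  }
  for (w in c(0.4, 1, 2.5)) {
    expect_equal(dwallenius(4, 5, 3, w), enum_wallenius(4, 5, 3, w),
                 tolerance = 1e-12)
    expect_equal(dwallenius(6, 6, 4, w), enum_wallenius(6, 6, 4, w),
                 tolerance = 1e-12)
  }
  # bias correction weakens apparent enrichment: at w > 1 the upper tail is
  # larger than the central hypergeometric tail
  expect_gte(pwallenius_upper(3, 6, 6, 4, 2.5),
             phyper(2, 6, 6, 4, lower.tail = FALSE))
})

test_that("gene-set enrichment weights odds by CpG counts", {
  ann <- data.frame(
    cpg_id = paste0("cg", 1:30),
    gene = rep(paste0("G", 1:12), c(1, 1, 2, 2, 3, 3, 4, 4, 1, 2, 3, 4)))
  sets <- list(up = paste0("G", c(7, 8, 12)),   # CpG-rich genes
               flat = paste0("G", c(1, 3, 9)))
  sel <- ann$cpg_id[ann$gene %in% c("G7", "G12", "G1")]
  res <- wallenius_gene_enrichment(sel, ann, sets)
  expect_equal(nrow(res), 2)
  expect_gt(res$w[res$set == "up"], 1)
  expect_lt(res$w[res$set == "flat"], 1)
  expect_true(all(res$p >= 0 & res$p <= 1))
  # equal CpG counts -> w = 1 and p equals the central hypergeometric
  ann_eq <- data.frame(cpg_id = paste0("cg", 1:24),
                       gene = rep(paste0("G", 1:12), each = 2))
  sel_eq <- ann_eq$cpg_id[ann_eq$gene %in% paste0("G", 1:3)]
  res_eq <- wallenius_gene_enrichment(sel_eq, ann_eq,
                                      list(s = paste0("G", c(1, 2, 5, 6))))
  expect_equal(res_eq$w, 1)
  expect_equal(res_eq$p, phyper(1, 4, 8, 3, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_warning(
    wallenius_gene_enrichment(sel_eq, ann_eq, list(empty = "NOPE")),
    "skipped")
})

test_that("relative enrichment matches closed forms and is 0 for self", {
  ann <- data.frame(cpg_id = paste0("cg", 1:1000),
                    chrom = "chr1", pos = seq(100L, by = 100L, length.out = 1000))
  ann$peak_Mono_DNase <- c(rep(TRUE, 30), rep(FALSE, 70),
                           rep(TRUE, 120), rep(FALSE, 780))
  # module = first 100 CpGs: 30 in-peak of 100; background 150/1000 -> RE 2
  assignment <- setNames(c(rep(1L, 100), rep(0L, 900)), ann$cpg_id)
  mods <- module_set_from_assignment(assignment)
  ce <- celltype_relative_enrichment(mods, "peak_Mono_DNase", ann)
  expect_equal(unname(ce$log2_re[1, 1]), 1.0, tolerance = 1e-12)
  # module entirely in peaks with background density 0.25 -> log2 RE = 2
  ann2 <- ann
  ann2$peak_Mono_DNase <- c(rep(TRUE, 100), rep(TRUE, 150), rep(FALSE, 750))
  # background density = 250/1000; make exactly 0.25 and module all in-peak
  ce2 <- celltype_relative_enrichment(mods, "peak_Mono_DNase", ann2)
  expect_equal(unname(ce2$log2_re[1, 1]), 2.0, tolerance = 1e-12)
  # the background against itself is exactly 0
  all_mod <- module_set_from_assignment(setNames(rep(1L, 1000), ann$cpg_id))
  ce3 <- celltype_relative_enrichment(all_mod, "peak_Mono_DNase", ann)
  expect_equal(unname(ce3$log2_re[1, 1]), 0)
  # zero-overlap cells are flagged, not -Inf
  empty_mod <- module_set_from_assignment(
    setNames(c(rep(0L, 30), rep(1L, 70), rep(0L, 900)), ann$cpg_id))
  ce4 <- celltype_relative_enrichment(empty_mod, "peak_Mono_DNase", ann)
  expect_true(is.na(ce4$log2_re[1, 1]))
  expect_true(ce4$counts$flagged[1])
})

test_that("BED-interval peak membership uses 0-based half-open semantics", {
  ann <- data.frame(cpg_id = paste0("cg", 1:4), chrom = "chr1",
                    pos = c(100L, 101L, 150L, 151L))
  bed <- data.frame(chrom = "chr1", start = 100L, end = 150L)  # covers 101..150
  member <- methmodsurv:::cpg_in_peaks(ann, bed)
  expect_identical(member, c(FALSE, TRUE, TRUE, FALSE))
  ann$peak_x_y <- member
  mods <- module_set_from_assignment(setNames(c(1L, 1L, 0L, 0L), ann$cpg_id))
  ce <- celltype_relative_enrichment(mods, list(x_y = bed), ann)
  expect_equal(ce$counts$k_m, 1)
  expect_equal(ce$counts$k_a, 2)
  tmp <- withr::local_tempfile(lines = c("chr1\t100\t150", "chr1\tbad\t200"))
  expect_error(read_bed(tmp), "line 2")
})

test_that("flag overlap tests cover direction conventions", {
  sc <- small_scene()
  ann <- sc$ann
  res <- flag_overlap_tests(sc$modules, ann, c("horvath", "polycomb_target"))
  expect_equal(nrow(res), 2 * 2)
  expect_true(all(res$p_upper >= 0 & res$p_upper <= 1))
  expect_error(flag_overlap_tests(sc$modules, ann, "nope"), "unknown flag")
  # flag covering every CpG: two-tailed p = 1 for every module
  ann$all_flag <- TRUE
  res_all <- flag_overlap_tests(sc$modules, ann, "all_flag")
  expect_true(all(res_all$p_two == 1))
  # module disjoint from a large flag: depletion, upper tail near 1
  ann$disjoint <- !(ann$cpg_id %in% sc$modules$modules[[1]]) &
    seq_len(nrow(ann)) <= 500
  res_d <- flag_overlap_tests(sc$modules, ann, "disjoint")
  expect_gt(res_d$p_upper[res_d$module == names(sc$modules$modules)[1]], 0.99)
})
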
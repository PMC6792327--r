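# Probit transform of p-values (z such that p = 1 - pnorm(z)), with clipping
# so z stays finite.
p_to_z <- function(p) stats::qnorm(clip_p(p), lower.tail = FALSE)

bin_index <- function(d, step, n_bins) {
  pmin(as.integer(floor((d - 1) / step)) + 1L, n_bins)
}

#' Distance-binned autocorrelation of EWAS z-scores
#'
#' Estimates the autocorrelation function (ACF) of probit-transformed EWAS
#' p-values as a function of genomic distance: for each half-open distance
#' bin `[lo, hi)` (width `step`, covering `(0, max_dist]`), the Pearson
#' correlation of z-values over all same-chromosome site pairs whose distance
#' falls in the bin. Bins with fewer than `min_pairs` pairs inherit the
#' nearest informative bin's estimate with a warning. For downstream use as a
#' covariance, estimates are clipped to `[0, 1)` in the `sigma` column; the
#' raw correlation is kept in `cor`.
#'
#' @param sites `data.frame` with `chrom`, `pos` (1-based), `p`, sorted by
#'   (chrom, pos); at least 2 sites.
#' @param max_dist maximum pair distance in bp (default 1000).
#' @param step bin width in bp (default 50).
#' @param min_pairs minimum pairs for a bin to be informative.
#' @return `data.frame` of class `acf_table` with lo, hi, cor, sigma,
#'   n_pairs; attributes `step` and `max_dist`.
#' @export
estimate_acf <- function(sites, max_dist = 1000, step = 50, min_pairs = 10) {
  stopifnot(nrow(sites) >= 2)
  check_sorted(sites)
  z <- p_to_z(sites$p)
  n_bins <- as.integer(ceiling(max_dist / step))
  zz <- vector("list", n_bins)
  pairs_a <- lapply(seq_len(n_bins), function(i) numeric(0))
  pairs_b <- lapply(seq_len(n_bins), function(i) numeric(0))
  for (ch in unique(sites$chrom)) {
    idx <- which(sites$chrom == ch)
    pos <- sites$pos[idx]
    zi <- z[idx]
    j0 <- 1L
    for (i in seq_along(idx)) {
      j <- i + 1L
      while (j <= length(idx) && pos[j] - pos[i] <= max_dist) {
        b <- bin_index(pos[j] - pos[i], step, n_bins)
        pairs_a[[b]] <- c(pairs_a[[b]], zi[i])
        pairs_b[[b]] <- c(pairs_b[[b]], zi[j])
        j <- j + 1L
      }
    }
  }
  n_pairs <- vapply(pairs_a, length, integer(1))
  est <- rep(NA_real_, n_bins)
  for (b in seq_len(n_bins)) {
    if (n_pairs[b] >= min_pairs &&
        stats::sd(pairs_a[[b]]) > 0 && stats::sd(pairs_b[[b]]) > 0) {
      est[b] <- stats::cor(pairs_a[[b]], pairs_b[[b]])
    } else if (n_pairs[b] >= 2 && n_pairs[b] < min_pairs) {
      est[b] <- NA_real_
    }
  }
  if (all(n_pairs == 0)) {
    warning("no same-chromosome pairs within max_dist; ACF set to zero")
    est[] <- 0
  } else if (anyNA(est)) {
    warning("ACF bins with too few pairs inherit the nearest informative bin")
    informative <- which(!is.na(est))
    if (length(informative) == 0) {
      est[] <- 0
    } else {
      for (b in which(is.na(est))) {
        est[b] <- est[informative[which.min(abs(informative - b))]]
      }
    }
  }
  out <- data.frame(lo = (seq_len(n_bins) - 1L) * step + 1L,
                    hi = seq_len(n_bins) * step + 1L,
                    cor = est,
                    sigma = pmin(pmax(est, 0), 1 - 1e-8),
                    n_pairs = n_pairs)
  attr(out, "step") <- step
  attr(out, "max_dist") <- n_bins * step
  class(out) <- c("acf_table", "data.frame")
  out
}

check_sorted <- function(sites) {
  o <- order(sites$chrom, sites$pos)
  if (!identical(o, seq_len(nrow(sites)))) {
    stop("sites must be sorted by (chrom, pos)")
  }
}

acf_sigma <- function(acf, d) {
  step <- attr(acf, "step")
  acf$sigma[bin_index(d, step, nrow(acf))]
}

#' Stouffer-Liptak-Kechris per-site p-value adjustment
#'
#' Adjusts each site's p-value by combining it with its neighbors within
#' `max_dist` on the same chromosome: with window z-scores `z_j` and
#' pairwise ACF values `sigma(d_jl)`, the combined z is
#' `z_c = sum(z_j) / sqrt(k + 2 * sum_{j<l} sigma(d_jl))` and the adjusted p
#' is `1 - pnorm(z_c)`. A singleton window returns the site's own p.
#'
#' @param sites sorted `data.frame` with `chrom`, `pos`, `p`.
#' @param acf an `acf_table` from [estimate_acf()].
#' @param max_dist neighborhood half-width (defaults to the ACF coverage).
#' @return Numeric vector of adjusted p-values, one per site.
#' @export
slk_adjust <- function(sites, acf, max_dist = attr(acf, "max_dist")) {
  check_sorted(sites)
  z <- p_to_z(sites$p)
  n <- nrow(sites)
  out <- numeric(n)
  for (ch in unique(sites$chrom)) {
    idx <- which(sites$chrom == ch)
    pos <- sites$pos[idx]
    zi <- z[idx]
    lo <- 1L
    hi <- 1L
    m <- length(idx)
    for (i in seq_len(m)) {
      while (lo <= m && pos[i] - pos[lo] > max_dist) lo <- lo + 1L
      while (hi < m && pos[hi + 1L] - pos[i] <= max_dist) hi <- hi + 1L
      w <- lo:hi
      k <- length(w)
      if (k == 1) {
        out[idx[i]] <- sites$p[idx[i]]
      } else {
        d <- stats::dist(pos[w])
        denom <- k + 2 * sum(acf_sigma(acf, as.vector(d)))
        zc <- sum(zi[w]) / sqrt(denom)
        out[idx[i]] <- stats::pnorm(zc, lower.tail = FALSE)
      }
    }
  }
  out
}

#' Find candidate regions of low adjusted p-values
#'
#' Maximal same-chromosome runs of sites with adjusted p below `threshold`
#' in which consecutive members are at most `max_gap` bp apart; runs with
#' fewer than `min_probes` sites are discarded. Region intervals use the
#' 0-based half-open convention `[first_pos - 1, last_pos)`.
#'
#' @param sites sorted `data.frame` with `chrom`, `pos`.
#' @param p_adj adjusted p-values from [slk_adjust()].
#' @param threshold inclusion threshold (default 0.1).
#' @param max_gap maximum gap between neighboring members (default 500 bp).
#' @param min_probes minimum sites per region (default 2).
#' @return `data.frame` with chrom, start, end, n_probes, and a list column
#'   `index` of member row indices into `sites`.
#' @export
find_regions <- function(sites, p_adj, threshold = 0.1, max_gap = 500,
                         min_probes = 2) {
  check_sorted(sites)
  below <- !is.na(p_adj) & p_adj < threshold
  regions <- list()
  for (ch in unique(sites$chrom)) {
    idx <- which(sites$chrom == ch & below)
    if (length(idx) == 0) next
    gap_break <- c(TRUE, diff(sites$pos[idx]) > max_gap)
    run <- cumsum(gap_break)
    for (r in unique(run)) {
      members <- idx[run == r]
      if (length(members) < min_probes) next
      regions[[length(regions) + 1L]] <- data.frame(
        chrom = ch,
        start = sites$pos[members[1]] - 1L,
        end = sites$pos[members[length(members)]],
        n_probes = length(members),
        index = I(list(members)))
    }
  }
  if (length(regions) == 0) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_probes = integer(0),
                      index = I(list())))
  }
  do.call(rbind, regions)
}

#' Stouffer-Liptak regional p-value
#'
#' Combines the raw (unadjusted) member p-values of a region under the
#' ACF-implied dependence: `z_c = sum(z_i) / sqrt(m + 2 * sum_{i<j}
#' sigma(d_ij))`, regional p `= 1 - pnorm(z_c)`. A single-member region
#' returns its member's p. Invariant to member ordering.
#'
#' @param member_sites `data.frame` with `pos` and `p` for the region members.
#' @param acf_extended an `acf_table` covering distances up to the region
#'   span.
#' @return The regional p-value.
#' @export
region_p <- function(member_sites, acf_extended) {
  m <- nrow(member_sites)
  if (m == 1) return(member_sites$p)
  z <- p_to_z(member_sites$p)
  d <- stats::dist(member_sites$pos)
  if (max(d) > attr(acf_extended, "max_dist")) {
    stop("extended ACF does not cover the region span")
  }
  denom <- m + 2 * sum(acf_sigma(acf_extended, as.vector(d)))
  stats::pnorm(sum(z) / sqrt(denom), lower.tail = FALSE)
}

#' Sidak correction with region-size-scaled effective tests
#'
#' The number of effective tests is the number of loci tested divided by the
#' number of loci in the region, `m = n_loci_tested / n_loci_in_region`, and
#' the corrected p is `1 - (1 - p)^m`, computed via `expm1`/`log1p` for
#' stability. `sidak_correct(p, N, N) = p` exactly.
#'
#' @param region_p regional p-value in \[0,1\].
#' @param n_loci_tested total number of loci in the scan.
#' @param n_loci_in_region number of loci in the region (>= 1).
#' @return The corrected p-value.
#' @export
sidak_correct <- function(region_p, n_loci_tested, n_loci_in_region) {
  if (any(region_p < 0 | region_p > 1)) stop("region_p outside [0,1]")
  stopifnot(n_loci_in_region >= 1, n_loci_tested >= n_loci_in_region)
  m <- n_loci_tested / n_loci_in_region
  -expm1(m * log1p(-region_p))
}

#' Call differentially methylated regions from EWAS p-values
#'
#' End-to-end comb-p style region calling: estimate the distance-binned ACF
#' (max distance 1 kb, step 50 bp), apply the Stouffer-Liptak-Kechris
#' per-site adjustment, find contiguous candidate regions (adjusted p below
#' 0.1, gaps at most 500 bp), recompute the ACF out to the maximum region
#' span, compute each region's Stouffer-Liptak p from the raw member
#' p-values, and apply the Sidak correction with region-size-scaled effective
#' tests. The direction summary counts the signs of member EWAS coefficients.
#'
#' @param ewas an `ewas_results` object (with chrom/pos attached) or a sorted
#'   `data.frame` with `chrom`, `pos`, `p` and optionally `coef`, `cpg_id`.
#' @param threshold,max_gap,min_probes see [find_regions()].
#' @param max_dist,step see [estimate_acf()].
#' @param sidak_basis `"loci"` (the default: effective tests = loci tested /
#'   loci in region) or `"bases"` (total bp span of tested sites / region
#'   width).
#' @return `data.frame` of class `dmr_records`, sorted by `sidak_p`, with
#'   chrom, start, end (0-based half-open), location (1-based inclusive
#'   string), n_probes, region_p, sidak_p, n_pos, n_neg, and member cpg ids.
#' @export
call_dmrs <- function(ewas, threshold = 0.1, max_gap = 500, min_probes = 2,
                      max_dist = 1000, step = 50,
                      sidak_basis = c("loci", "bases")) {
  sidak_basis <- match.arg(sidak_basis)
  sites <- if (inherits(ewas, "ewas_results")) ewas$results else ewas
  stopifnot(all(c("chrom", "pos", "p") %in% names(sites)))
  sites <- sites[!is.na(sites$p), , drop = FALSE]
  sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
  rownames(sites) <- NULL
  if (nrow(sites) < 100) stop("need EWAS p-values for at least 100 sites")
  acf <- estimate_acf(sites, max_dist = max_dist, step = step)
  p_adj <- slk_adjust(sites, acf)
  regions <- find_regions(sites, p_adj, threshold = threshold,
                          max_gap = max_gap, min_probes = min_probes)
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), location = character(0),
                      n_probes = integer(0), region_p = numeric(0),
                      sidak_p = numeric(0), n_pos = integer(0),
                      n_neg = integer(0), cpgs = character(0))
  if (nrow(regions) == 0) return(structure(empty, class = c("dmr_records", "data.frame")))
  max_span <- max(regions$end - regions$start)
  acf_ext <- suppressWarnings(estimate_acf(
    sites, max_dist = max(max_dist, ceiling(max_span / step) * step),
    step = step))
  n_tested <- nrow(sites)
  total_span <- sum(tapply(sites$pos, sites$chrom, function(x) diff(range(x))))
  out <- lapply(seq_len(nrow(regions)), function(i) {
    members <- sites[regions$index[[i]], , drop = FALSE]
    rp <- region_p(members, acf_ext)
    m_eff_basis <- if (sidak_basis == "loci") {
      c(n_tested, nrow(members))
    } else {
      c(total_span, regions$end[i] - regions$start[i])
    }
    sp <- sidak_correct(rp, m_eff_basis[1], m_eff_basis[2])
    signs <- if ("coef" %in% names(members)) sign(members$coef) else numeric(0)
    data.frame(
      chrom = regions$chrom[i], start = regions$start[i], end = regions$end[i],
      location = sprintf("%s:%d-%d", regions$chrom[i], regions$start[i] + 1L,
                         regions$end[i]),
      n_probes = regions$n_probes[i], region_p = rp, sidak_p = sp,
      n_pos = sum(signs > 0), n_neg = sum(signs < 0),
      cpgs = if ("cpg_id" %in% names(members))
               paste(members$cpg_id, collapse = ",") else NA_character_,
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$sidak_p), ]
  rownames(res) <- NULL
  structure(res, class = c("dmr_records", "data.frame"))
}
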
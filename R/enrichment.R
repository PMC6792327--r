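#' Exact hypergeometric overlap test
#'
#' Tests the overlap between a query CpG set and an annotation CpG set
#' against a common background: upper tail `P(X >= k)`, lower tail
#' `P(X <= k)`, and a two-tailed p by the minimum-likelihood method (the sum
#' of all outcome probabilities not exceeding that of the observed overlap),
#' capped at 1.
#'
#' @param query,annotation character vectors of CpG ids, both subsets of
#'   `background`.
#' @param background character vector of background CpG ids (typically the
#'   CpGs surviving QC).
#' @return List of class `overlap_enrichment`: k, n, K, N, expected,
#'   p_upper, p_lower, p_two.
#' @export
hypergeom_overlap <- function(query, annotation, background) {
  if (length(background) == 0) stop("empty background")
  if (!all(query %in% background)) stop("query must be a subset of background")
  if (!all(annotation %in% background)) stop("annotation must be a subset of background")
  N <- length(unique(background))
  K <- length(unique(annotation))
  n <- length(unique(query))
  k <- length(intersect(unique(query), unique(annotation)))
  hypergeom_counts(k, n, K, N)
}

# Core tail computation on counts (also used by flag tests).
hypergeom_counts <- function(k, n, K, N) {
  stopifnot(k >= max(0, n + K - N), k <= min(n, K))
  p_upper <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  p_lower <- stats::phyper(k, K, N - K, n)
  support <- max(0, n + K - N):min(n, K)
  d <- stats::dhyper(support, K, N - K, n)
  d_obs <- stats::dhyper(k, K, N - K, n)
  p_two <- min(1, sum(d[d <= d_obs * (1 + 1e-7)]))
  structure(list(k = k, n = n, K = K, N = N, expected = n * K / N,
                 p_upper = p_upper, p_lower = p_lower, p_two = p_two),
            class = "overlap_enrichment")
}

#' Wallenius' noncentral hypergeometric distribution
#'
#' Probability mass and upper tail of the number of "set" genes among `n`
#' sequential draws without replacement from `m1` set genes (each with odds
#' weight `w`) and `m2` non-set genes (weight 1). Computed by the exact
#' sequential-draw recursion (no quadrature), which reduces to the central
#' hypergeometric exactly at `w = 1`.
#'
#' @param m1 number of set genes in the universe.
#' @param m2 number of non-set genes.
#' @param n number of draws (selected genes).
#' @param w odds weight of set genes (> 0).
#' @return `dwallenius`: numeric vector of `P(X = x)` for `x = 0..n`.
#' @export
dwallenius <- function(m1, m2, n, w) {
  stopifnot(m1 >= 0, m2 >= 0, n >= 0, n <= m1 + m2, w > 0)
  p <- 1 # state vector over x = 0..j after j draws
  if (n == 0) return(1)
  for (j in seq_len(n)) {
    x <- 0:(j - 1)
    succ_w <- w * pmax(m1 - x, 0)
    fail_w <- pmax(m2 - (j - 1 - x), 0)
    tot <- succ_w + fail_w
    ps <- ifelse(tot > 0, succ_w / tot, 0)
    p <- c(p * (1 - ps), 0) + c(0, p * ps)
  }
  p
}

#' @rdname dwallenius
#' @param k observed overlap; the upper tail is `P(X >= k)`.
#' @return `pwallenius_upper`: the upper-tail probability.
#' @export
pwallenius_upper <- function(k, m1, m2, n, w) {
  pmf <- dwallenius(m1, m2, n, w)
  sum(pmf[seq.int(k + 1, n + 1)])
}

#' Gene-set enrichment with CpG-count bias correction
#'
#' Gene ontology style enrichment of the genes touched by a CpG set, with the
#' probe-count bias handled as in gometh-style analyses: a gene is "selected"
#' if any of its CpGs is in the selected set, the prior odds of selection are
#' proportional to the gene's CpG count, and each gene set is tested with
#' Wallenius' noncentral hypergeometric distribution using the odds weight
#' `w = mean(CpGs per gene | gene in set) / mean(CpGs per gene | gene not in
#' set)`.
#'
#' @param selected_cpgs character vector of selected CpG ids (e.g. a module).
#' @param annotation annotation with `cpg_id` and `gene` columns.
#' @param gene_sets named list of gene-id vectors (GMT-shaped; see
#'   [read_gmt()]).
#' @param cpgs_per_gene optional named count vector; defaults to the CpG
#'   counts in `annotation`.
#' @return `data.frame` with one row per set: set, n_genes_in_set,
#'   n_selected_in_set, w, expected (mean under the biased null), p.
#' @export
wallenius_gene_enrichment <- function(selected_cpgs, annotation, gene_sets,
                                      cpgs_per_gene = NULL) {
  if (is.null(cpgs_per_gene)) {
    tab <- table(annotation$gene)
    cpgs_per_gene <- stats::setNames(as.integer(tab), names(tab))
  }
  stopifnot(all(cpgs_per_gene >= 1))
  universe <- names(cpgs_per_gene)
  sel_genes <- unique(annotation$gene[annotation$cpg_id %in% selected_cpgs])
  sel_genes <- intersect(sel_genes, universe)
  n <- length(sel_genes)
  out <- lapply(names(gene_sets), function(nm) {
    genes_in <- intersect(gene_sets[[nm]], universe)
    if (length(genes_in) == 0) {
      warning("gene set '", nm, "' has no annotated genes; skipped")
      return(NULL)
    }
    m1 <- length(genes_in)
    m2 <- length(universe) - m1
    x <- length(intersect(sel_genes, genes_in))
    w <- mean(cpgs_per_gene[genes_in]) /
      mean(cpgs_per_gene[setdiff(universe, genes_in)])
    pmf <- dwallenius(m1, m2, n, w)
    data.frame(set = nm, n_genes_in_set = m1, n_selected_in_set = x, w = w,
               expected = sum((0:n) * pmf),
               p = sum(pmf[seq.int(x + 1, n + 1)]),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (!is.null(res)) rownames(res) <- NULL
  res
}

#' Cell type-specific chromatin peak relative enrichment
#'
#' For each module and each (cell type, chromatin mark) peak set, the
#' relative enrichment is the in-peak fraction of module CpGs over the
#' in-peak fraction of all background CpGs,
#' `RE = (k_m / n_m) / (k_a / n_a)`, reported as `log2(RE)`. Cells where the
#' module or background overlap is zero are flagged (NA) rather than
#' reported as infinite.
#'
#' @param modules a `module_set`.
#' @param peaks either a character vector of `peak_*` flag column names in
#'   `annotation`, or a named list of BED-style `data.frame`s
#'   (chrom, start, end; 0-based half-open) or file paths (see [read_bed()]).
#' @param annotation annotation of the background CpGs (all tested CpGs).
#' @return List of class `celltype_enrichment`: `log2_re` (modules x peak
#'   sets), `counts` (long `data.frame` with k_m, n_m, k_a, n_a, flagged).
#' @export
celltype_relative_enrichment <- function(modules, peaks, annotation) {
  if (is.character(peaks)) {
    stopifnot(all(peaks %in% names(annotation)))
    membership <- sapply(peaks, function(pc) annotation[[pc]])
  } else {
    membership <- sapply(names(peaks), function(nm) {
      bed <- peaks[[nm]]
      if (is.character(bed)) bed <- read_bed(bed)
      cpg_in_peaks(annotation, bed)
    })
  }
  membership <- matrix(membership, nrow = nrow(annotation),
                       dimnames = list(annotation$cpg_id, colnames(membership)))
  n_a <- nrow(annotation)
  k_a <- colSums(membership)
  mods <- modules$modules
  log2_re <- matrix(NA_real_, length(mods), ncol(membership),
                    dimnames = list(names(mods), colnames(membership)))
  counts <- list()
  for (i in seq_along(mods)) {
    members <- intersect(mods[[i]], rownames(membership))
    n_m <- length(members)
    k_m <- colSums(membership[members, , drop = FALSE])
    flagged <- k_m == 0 | k_a == 0
    re <- (k_m / n_m) / (k_a / n_a)
    log2_re[i, !flagged] <- log2(re[!flagged])
    counts[[i]] <- data.frame(module = names(mods)[i],
                              peak = colnames(membership),
                              k_m = k_m, n_m = n_m, k_a = k_a, n_a = n_a,
                              flagged = flagged, row.names = NULL)
  }
  structure(list(log2_re = log2_re, counts = do.call(rbind, counts)),
            class = "celltype_enrichment")
}

# Peak membership of annotation CpGs: BED intervals are 0-based half-open,
# so a CpG at 1-based pos is in [start, end) iff start + 1 <= pos <= end.
cpg_in_peaks <- function(annotation, bed) {
  gr_peaks <- GenomicRanges::GRanges(bed$chrom,
                                     IRanges::IRanges(bed$start + 1L, bed$end))
  gr_cpgs <- GenomicRanges::GRanges(annotation$chrom,
                                    IRanges::IRanges(annotation$pos, annotation$pos))
  GenomicRanges::countOverlaps(gr_cpgs, gr_peaks) > 0
}

#' Module overlap tests against annotation flags
#'
#' One exact hypergeometric overlap test per (module, flag) pair, with the
#' background being all annotated (tested) CpGs. Epigenetic-clock and
#' Polycomb tests are read on the upper tail (the reported enrichment
#' direction); locus-category tests use the two-tailed p — both tails are
#' returned.
#'
#' @param modules a `module_set`.
#' @param annotation annotation containing the logical flag columns.
#' @param flags names of logical columns in `annotation` to test.
#' @return `data.frame` with one row per (module, flag): k, n, K, N,
#'   expected, p_upper, p_two.
#' @export
flag_overlap_tests <- function(modules, annotation, flags) {
  unknown <- setdiff(flags, names(annotation))
  if (length(unknown) > 0) stop("unknown flag(s): ", paste(unknown, collapse = ", "))
  N <- nrow(annotation)
  out <- list()
  for (nm in names(modules$modules)) {
    members <- modules$modules[[nm]]
    in_mod <- annotation$cpg_id %in% members
    for (fl in flags) {
      flag <- as.logical(annotation[[fl]])
      h <- hypergeom_counts(sum(in_mod & flag), sum(in_mod), sum(flag), N)
      out[[length(out) + 1L]] <- data.frame(
        module = nm, flag = fl, k = h$k, n = h$n, K = h$K, N = h$N,
        expected = h$expected, p_upper = h$p_upper, p_two = h$p_two,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Read a GMT gene-set file
#'
#' @param path GMT file: one set per line, tab-separated
#'   `name<TAB>description<TAB>gene1<TAB>gene2...`.
#' @return Named list of gene-id character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) < 3)
  if (length(bad) > 0) stop("malformed GMT line ", bad[1])
  stats::setNames(lapply(parts, function(x) x[-(1:2)]),
                  vapply(parts, `[`, character(1), 1))
}

#' Read a BED file of peak intervals
#'
#' @param path BED file with at least chrom, start, end columns (0-based
#'   half-open).
#' @return `data.frame` with chrom, start, end.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(parts)) {
    x <- parts[[i]]
    if (length(x) < 3 || is.na(suppressWarnings(as.integer(x[2]))) ||
        is.na(suppressWarnings(as.integer(x[3])))) {
      stop("malformed BED line ", i, " in ", path)
    }
  }
  data.frame(chrom = vapply(parts, `[`, character(1), 1),
             start = as.integer(vapply(parts, `[`, character(1), 2)),
             end = as.integer(vapply(parts, `[`, character(1), 3)),
             stringsAsFactors = FALSE)
}
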
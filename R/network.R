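#' Network parameters for module detection
#'
#' @param power soft-threshold exponent applied to |correlation| (default 8).
#' @param block_size maximum CpGs per block for blockwise detection.
#' @param precluster_subsample number of subjects used in the k-means
#'   pre-clustering step (default 100).
#' @param min_module_size smallest retained module.
#' @param merge_eigen_cor modules whose eigenCpGs correlate above this are
#'   merged (default 0.75, the conventional merge height 0.25).
#' @param cut_height static branch-cut height on the 1-TOM dendrogram.
#' @return List of class `network_params`.
#' @export
network_params <- function(power = 8, block_size = 20000,
                           precluster_subsample = 100, min_module_size = 20,
                           merge_eigen_cor = 0.75, cut_height = 0.999) {
  stopifnot(power >= 1, block_size >= min_module_size, min_module_size >= 2,
            merge_eigen_cor > 0, merge_eigen_cor < 1,
            cut_height > 0, cut_height <= 1)
  structure(list(power = power, block_size = block_size,
                 precluster_subsample = precluster_subsample,
                 min_module_size = min_module_size,
                 merge_eigen_cor = merge_eigen_cor,
                 cut_height = cut_height),
            class = "network_params")
}

# Unsigned weighted adjacency |cor|^power with zero diagonal. Constant CpGs
# get zero adjacency with a warning.
adjacency_matrix <- function(x, power = 8) {
  r <- suppressWarnings(stats::cor(x))
  if (anyNA(r)) {
    warning("constant CpGs present; their correlations treated as 0")
    r[is.na(r)] <- 0
  }
  a <- abs(r)^power
  diag(a) <- 0
  a
}

#' Soft-threshold diagnostics
#'
#' For each candidate power, builds the unsigned adjacency on a random CpG
#' subset, computes connectivities `k_i = sum_j a_ij`, and fits
#' `log10(freq(k)) ~ log10(k)` over equal-count bins; the fit R-squared
#' measures approximate scale-free topology, while mean connectivity tracks
#' how aggressively the power shrinks the network.
#'
#' @param beta samples x CpGs beta matrix.
#' @param powers candidate soft-threshold powers.
#' @param n_cpg_subset CpGs sampled for the diagnostic (all if fewer).
#' @param n_bins number of equal-count connectivity bins.
#' @param seed integer seed for the CpG subsample.
#' @return `data.frame` with columns power, scale_free_R2, slope,
#'   mean_connectivity.
#' @export
pick_soft_threshold <- function(beta, powers = c(1:10, 12, 14, 16, 18, 20),
                                n_cpg_subset = 2000, n_bins = 10, seed = 1) {
  stopifnot(nrow(beta) >= 3, ncol(beta) >= 50)
  with_seed(seed, {
    idx <- if (ncol(beta) > n_cpg_subset) sample.int(ncol(beta), n_cpg_subset)
           else seq_len(ncol(beta))
    r <- suppressWarnings(stats::cor(beta[, idx]))
    if (anyNA(r)) {
      warning("constant CpGs present; their correlations treated as 0")
      r[is.na(r)] <- 0
    }
    ar <- abs(r)
    diag(ar) <- 0
    out <- lapply(powers, function(p) {
      a <- ar^p
      k <- colSums(a)
      bin <- cut(k, n_bins, include.lowest = TRUE)  # equal-width bins
      freq <- tabulate(bin, nbins = nlevels(bin))
      kmean <- tapply(k, bin, mean)
      okbin <- !is.na(kmean) & freq > 0 & kmean > 0
      r2 <- slope <- NA_real_
      if (sum(okbin) >= 3) {
        fit <- stats::lm(log10(freq[okbin]) ~ log10(kmean[okbin]))
        r2 <- summary(fit)$r.squared
        slope <- unname(stats::coef(fit)[2])
      }
      data.frame(power = p, scale_free_R2 = r2, slope = slope,
                 mean_connectivity = mean(k), row.names = NULL)
    })
    do.call(rbind, out)
  })
}

#' Topological overlap matrix
#'
#' Unsigned TOM: `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 -
#' a_ij)` with unit diagonal, a shared-neighbor similarity built from a
#' soft-thresholded correlation network.
#'
#' @param adjacency symmetric matrix with entries in \[0,1\]; the diagonal is
#'   ignored (treated as zero).
#' @return Symmetric matrix in \[0,1\] with unit diagonal.
#' @export
tom_matrix <- function(adjacency) {
  if (max(abs(adjacency - t(adjacency))) > 1e-10) stop("adjacency is not symmetric")
  a <- adjacency
  diag(a) <- 0
  if (min(a) < 0 || max(a) > 1) stop("adjacency entries must lie in [0,1]")
  l <- a %*% a
  k <- rowSums(a)
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / denom
  diag(tom) <- 1
  tom
}

# Assign CpGs to blocks of at most block_size by k-means on a subject
# subsample (CpGs standardized, so Euclidean distance tracks correlation).
assign_blocks <- function(beta, block_size, precluster_subsample) {
  n_cpgs <- ncol(beta)
  if (n_cpgs <= block_size) {
    centers <- max(2L, as.integer(ceiling(n_cpgs / block_size)) * 2L)
  } else {
    centers <- as.integer(ceiling(n_cpgs / block_size)) * 2L
  }
  nsub <- min(precluster_subsample, nrow(beta))
  if (nsub < precluster_subsample) {
    warning("pre-clustering subsample clipped to ", nsub, " subjects")
  }
  sub <- sample.int(nrow(beta), nsub)
  x <- t(scale(beta[sub, , drop = FALSE]))
  x[is.na(x)] <- 0
  km <- stats::kmeans(x, centers = centers, iter.max = 50, nstart = 1)
  blocks <- km$cluster
  # split oversized blocks by distance-to-center order
  repeat {
    sizes <- table(blocks)
    big <- names(sizes)[sizes > block_size]
    if (length(big) == 0) break
    for (b in big) {
      idx <- which(blocks == as.integer(b))
      d <- rowSums((x[idx, , drop = FALSE] -
                      matrix(km$centers[as.integer(b), ], length(idx),
                             ncol(x), byrow = TRUE))^2)
      ord <- idx[order(d)]
      n_chunks <- ceiling(length(idx) / block_size)
      chunk <- rep(seq_len(n_chunks), each = block_size)[seq_along(ord)]
      newlab <- max(blocks) + seq_len(n_chunks - 1)
      for (i in seq_len(n_chunks - 1)) blocks[ord[chunk == i + 1]] <- newlab[i]
    }
  }
  blocks
}

#' Blockwise module detection on a CpG correlation network
#'
#' Detects co-methylation modules: (1) CpGs are pre-clustered into blocks of
#' at most `block_size` by k-means on a random subject subsample; (2) within
#' each block, Pearson correlation -> unsigned soft-threshold adjacency ->
#' topological overlap -> average-linkage clustering of 1-TOM -> static
#' branch cut at `cut_height`, keeping clusters of at least
#' `min_module_size`; (3) eigenCpGs are computed and module pairs whose
#' eigenCpGs correlate above `merge_eigen_cor` are merged iteratively;
#' (4) modules are relabeled by descending size, with 0 ("grey") for
#' unassigned CpGs.
#'
#' @param beta samples x CpGs beta matrix.
#' @param params a [network_params()] object.
#' @param seed integer seed (pre-clustering and subsampling).
#' @return List of class `module_set`: `assignment` (named integer vector,
#'   0 = unassigned), `modules` (list of member CpG ids), `colors` (label ->
#'   color alias), `params`.
#' @export
detect_modules <- function(beta, params = network_params(), seed = 1) {
  with_seed(seed, {
    n_cpgs <- ncol(beta)
    cpg_ids <- colnames(beta) %||% as.character(seq_len(n_cpgs))
    colnames(beta) <- cpg_ids
    blocks <- assign_blocks(beta, params$block_size, params$precluster_subsample)
    assignment <- stats::setNames(integer(n_cpgs), cpg_ids)
    next_label <- 1L
    for (b in sort(unique(blocks))) {
      idx <- which(blocks == b)
      if (length(idx) < params$min_module_size) next
      a <- adjacency_matrix(beta[, idx, drop = FALSE], params$power)
      tom <- tom_matrix(a)
      hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
      cl <- stats::cutree(hc, h = params$cut_height)
      for (lab in unique(cl)) {
        members <- idx[cl == lab]
        if (length(members) >= params$min_module_size) {
          assignment[members] <- next_label
          next_label <- next_label + 1L
        }
      }
    }
    assignment <- merge_similar_modules(beta, assignment, params$merge_eigen_cor)
    relabel_modules(assignment, cpg_ids, params)
  })
}

# Iteratively merge the most-correlated eigenCpG pair above the threshold.
merge_similar_modules <- function(beta, assignment, merge_eigen_cor) {
  repeat {
    labs <- setdiff(sort(unique(assignment)), 0L)
    if (length(labs) < 2) break
    scores <- sapply(labs, function(l) {
      module_eigen_score(beta[, assignment == l, drop = FALSE])
    })
    cc <- stats::cor(scores)
    diag(cc) <- 0
    if (max(cc) <= merge_eigen_cor) break
    ij <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    keep <- labs[min(ij)]
    drop <- labs[max(ij)]
    assignment[assignment == drop] <- keep
  }
  assignment
}

# First-PC score of a standardized CpG block (orientation: positive
# correlation with the mean member profile).
module_eigen_score <- function(x) {
  xs <- scale(x)
  xs[, apply(x, 2, stats::sd) == 0] <- 0
  sv <- svd(xs, nu = 1, nv = 1)
  score <- xs %*% sv$v[, 1]
  if (stats::cor(score, rowMeans(xs)) < 0) score <- -score
  as.vector(score)
}

relabel_modules <- function(assignment, cpg_ids, params) {
  labs <- setdiff(sort(unique(assignment)), 0L)
  if (length(labs) == 0) {
    return(structure(list(assignment = stats::setNames(integer(length(assignment)),
                                                       cpg_ids),
                          modules = list(), colors = c(grey = 0L),
                          params = params),
                     class = "module_set"))
  }
  sizes <- vapply(labs, function(l) sum(assignment == l), integer(1))
  ord <- labs[order(-sizes)]
  new <- stats::setNames(integer(length(assignment)), cpg_ids)
  for (i in seq_along(ord)) new[assignment == ord[i]] <- i
  modules <- lapply(seq_along(ord), function(i) cpg_ids[new == i])
  colors <- c(grey = 0L)
  if (length(ord) > 0) {
    colors <- stats::setNames(0:length(ord), c("grey", module_colors(length(ord))))
    names(modules) <- module_colors(length(ord))
  }
  structure(list(assignment = new, modules = modules, colors = colors,
                 params = params),
            class = "module_set")
}

#' Build a module_set from a known assignment
#'
#' Convenience constructor used when the module membership is given (for
#' example the ground truth of a synthetic cohort) rather than detected.
#'
#' @param assignment named integer vector, 0 = unassigned.
#' @param params optional [network_params()].
#' @return A `module_set`.
#' @export
module_set_from_assignment <- function(assignment, params = network_params()) {
  relabel_modules(assignment, names(assignment), params)
}

#' Compute module eigenCpGs
#'
#' For each module, member CpGs are standardized (mean 0, sd 1 across
#' samples) and decomposed by SVD; the first right singular vector gives the
#' member weights (unit norm), scores are the standardized data times the
#' weights, and the orientation is flipped so the score correlates
#' nonnegatively with the mean standardized member profile. Variance
#' explained is the first squared singular value over the total.
#'
#' @param beta samples x CpGs beta matrix (the defining cohort).
#' @param modules a `module_set`.
#' @return List of class `module_eigenvectors` with per-module `weights`,
#'   `center`, `scale`, `variance_explained`, plus a `scores` matrix
#'   (samples x modules) as attribute-free element.
#' @export
compute_eigencpgs <- function(beta, modules) {
  mods <- modules$modules
  stopifnot(length(mods) >= 1)
  n <- nrow(beta)
  scores <- matrix(NA_real_, n, length(mods),
                   dimnames = list(rownames(beta), names(mods)))
  ev <- vector("list", length(mods))
  names(ev) <- names(mods)
  for (i in seq_along(mods)) {
    members <- mods[[i]]
    stopifnot(length(members) >= 2)
    x <- beta[, members, drop = FALSE]
    ctr <- colMeans(x)
    scl <- apply(x, 2, stats::sd)
    zero <- scl == 0
    if (any(zero)) {
      warning(sum(zero), " zero-variance CpGs dropped from module ", names(mods)[i])
      x <- x[, !zero, drop = FALSE]
      ctr <- ctr[!zero]
      scl <- scl[!zero]
      members <- members[!zero]
    }
    xs <- scale(x, center = ctr, scale = scl)
    sv <- svd(xs)
    w <- sv$v[, 1]
    score <- xs %*% w
    if (stats::cor(score, rowMeans(xs)) < 0) {
      w <- -w
      score <- -score
    }
    ev[[i]] <- list(weights = stats::setNames(w, members), center = ctr,
                    scale = scl,
                    variance_explained = sv$d[1]^2 / sum(sv$d^2))
    scores[, i] <- score
  }
  structure(list(eigenvectors = ev, scores = scores),
            class = "module_eigenvectors")
}

#' Project eigenCpG weights onto a new cohort
#'
#' Applies defining-cohort principal-component weights to a replication
#' cohort: the new cohort's CpGs are standardized with the *new* cohort's
#' means and sds, missing CpGs are dropped with the weight vector
#' renormalized to unit norm (at least 90% of weighted CpGs must be present),
#' and scores are the standardized data times the weights.
#'
#' @param eigen a `module_eigenvectors` object from [compute_eigencpgs()].
#' @param beta_new samples x CpGs beta matrix of the new cohort.
#' @param min_overlap minimum fraction of weighted CpGs required (0.9).
#' @return samples x modules score matrix.
#' @export
project_eigencpgs <- function(eigen, beta_new, min_overlap = 0.9) {
  ev <- eigen$eigenvectors
  scores <- matrix(NA_real_, nrow(beta_new), length(ev),
                   dimnames = list(rownames(beta_new), names(ev)))
  for (i in seq_along(ev)) {
    w <- ev[[i]]$weights
    present <- names(w) %in% colnames(beta_new)
    if (mean(present) < min_overlap) {
      stop("only ", round(100 * mean(present)), "% of module '", names(ev)[i],
           "' CpGs present in the new cohort; missing: ",
           paste(utils::head(names(w)[!present], 5), collapse = ", "),
           if (sum(!present) > 5) ", ..." else "")
    }
    w <- w[present]
    w <- w / sqrt(sum(w^2))
    x <- beta_new[, names(w), drop = FALSE]
    xs <- scale(x)
    xs[, apply(x, 2, stats::sd) == 0] <- 0
    scores[, i] <- xs %*% w
  }
  scores
}

#' Permutation-based module preservation statistics
#'
#' Measures whether a module found in a discovery cohort remains a module in
#' a test cohort, via two statistics: density (mean off-diagonal within-module
#' adjacency in the test data) and connectivity (correlation between the
#' discovery and test intramodular connectivity vectors). Each is converted
#' to a permutation Z against `n_perm` random CpG sets of equal size drawn
#' from unassigned CpGs, and `Z_summary` is their mean. Values above 10 are
#' conventionally read as strong preservation.
#'
#' @param beta_disc,beta_test discovery and test beta matrices sharing the
#'   module CpGs.
#' @param modules a `module_set`.
#' @param n_perm number of permutations (must be positive).
#' @param seed integer seed.
#' @param power soft-threshold power for the adjacencies.
#' @return `data.frame` with Z_density, Z_connectivity, Z_summary and the
#'   observed statistics per module.
#' @export
module_preservation <- function(beta_disc, beta_test, modules, n_perm = 100,
                                seed = 1, power = 8) {
  if (n_perm <= 0) stop("permutations required")
  mods <- modules$modules
  pool <- names(modules$assignment)[modules$assignment == 0]
  pool <- intersect(pool, intersect(colnames(beta_disc), colnames(beta_test)))
  with_seed(seed, {
    out <- lapply(names(mods), function(nm) {
      members <- mods[[nm]]
      stopifnot(all(members %in% colnames(beta_disc)),
                all(members %in% colnames(beta_test)))
      obs <- preservation_stats(beta_disc, beta_test, members, power)
      size <- length(members)
      replace <- size > length(pool)
      if (replace) warning("null pool smaller than module '", nm,
                           "'; sampling with replacement")
      null <- replicate(n_perm, {
        rnd <- sample(pool, size, replace = replace)
        unlist(preservation_stats(beta_disc, beta_test, rnd, power))
      })
      z_den <- perm_z(obs$mean_adj, null["mean_adj", ])
      z_con <- perm_z(obs$cor_kim, null["cor_kim", ])
      data.frame(module = nm, size = size,
                 mean_adj = obs$mean_adj, cor_kim = obs$cor_kim,
                 Z_density = z_den, Z_connectivity = z_con,
                 Z_summary = (z_den + z_con) / 2, n_permutations = n_perm)
    })
    do.call(rbind, out)
  })
}

# Permutation Z with a degenerate-null guard: when the null statistic has
# (numerically) zero spread, Z is 0 if the observation matches the null and
# +/-Inf otherwise (arises e.g. for connectivity when test data = discovery
# data, where every correlation is exactly 1).
perm_z <- function(obs, null) {
  m <- mean(null)
  s <- stats::sd(null)
  if (!is.finite(s) || s < 1e-12) {
    if (abs(obs - m) < 1e-8) return(0)
    return(sign(obs - m) * Inf)
  }
  (obs - m) / s
}

preservation_stats <- function(beta_disc, beta_test, members, power) {
  a_test <- adjacency_matrix(beta_test[, members, drop = FALSE], power)
  a_disc <- adjacency_matrix(beta_disc[, members, drop = FALSE], power)
  m <- length(members)
  mean_adj <- sum(a_test) / (m * (m - 1))
  cor_kim <- stats::cor(rowSums(a_disc), rowSums(a_test))
  list(mean_adj = mean_adj, cor_kim = cor_kim)
}
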
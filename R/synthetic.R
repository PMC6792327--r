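#' Generate a synthetic 450K-style CpG annotation table
#'
#' Builds an annotation mirroring the Illumina 450K manifest fields the
#' pipeline consumes: CpG id, chromosome, 1-based position, a gene label,
#' gene-region group, island relation, epigenetic-clock membership flags,
#' Polycomb-target status and per (cell type, chromatin mark) peak-membership
#' flags. Inter-CpG gaps are drawn from a mixture of short (< 500 bp, so that
#' runs of CpGs can form DMRs) and long (> 1 kb) gaps.
#'
#' @param n_cpgs number of CpGs (rows).
#' @param n_chroms number of chromosomes to spread CpGs over.
#' @param clock_size number of CpGs flagged per clock (default 353, the size
#'   of the Horvath DNAm-age predictor).
#' @param peak_density probability that a CpG falls inside a chromatin peak,
#'   per (cell type, mark) pair. Either a single value or a named vector over
#'   the generated `peak_<celltype>_<mark>` columns.
#' @param seed integer seed; the table is deterministic given the seed.
#' @param cell_types,marks cell types and chromatin marks for peak flags.
#' @param clocks names of the clock flag columns.
#' @param mean_cpgs_per_gene average number of consecutive CpGs sharing a gene
#'   label.
#' @param polycomb_rate marginal probability of the Polycomb-target flag.
#' @param short_gap_prob probability that the gap to the next CpG is short
#'   (10-450 bp) rather than long (> 1 kb).
#' @return A `data.frame` sorted by (chrom, pos) with one row per CpG.
#' @export
generate_annotation <- function(n_cpgs, n_chroms = 2, clock_size = 353,
                                peak_density = 0.1, seed = 1,
                                cell_types = c("Mono", "NK", "Tcell", "Bcell", "HSC"),
                                marks = c("DNase", "H3K4me1", "H3K4me3"),
                                clocks = c("horvath", "hannum", "phenoage"),
                                mean_cpgs_per_gene = 5,
                                polycomb_rate = 0.1,
                                short_gap_prob = 0.7) {
  if (n_cpgs < 1) stop("empty annotation")
  if (clock_size > n_cpgs) stop("clock larger than array")
  stopifnot(all(peak_density >= 0 & peak_density <= 1))
  with_seed(seed, {
    chrom_of <- sort(rep_len(seq_len(n_chroms), n_cpgs))
    pos <- integer(n_cpgs)
    for (ch in seq_len(n_chroms)) {
      idx <- which(chrom_of == ch)
      m <- length(idx)
      short <- stats::runif(m) < short_gap_prob
      gaps <- ifelse(short,
                     sample(10:450, m, replace = TRUE),
                     sample(1001:20000, m, replace = TRUE))
      pos[idx] <- 1000L + cumsum(gaps)
    }
    ann <- data.frame(
      cpg_id = sprintf("cg%08d", seq_len(n_cpgs)),
      chrom = paste0("chr", chrom_of),
      pos = pos,
      stringsAsFactors = FALSE
    )
    # consecutive CpGs share genes, with geometric run lengths
    gene_runs <- pmax(1L, stats::rgeom(n_cpgs, 1 / mean_cpgs_per_gene) + 1L)
    gene_idx <- rep(seq_along(gene_runs), gene_runs)[seq_len(n_cpgs)]
    ann$gene <- sprintf("GENE%05d", gene_idx)
    ann$gene_group <- sample(
      c("TSS1500", "TSS200", "5UTR", "1stExon", "Body", "3UTR", "intergenic"),
      n_cpgs, replace = TRUE,
      prob = c(0.10, 0.08, 0.08, 0.05, 0.35, 0.04, 0.30))
    ann$island_relation <- sample(
      c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf", "OpenSea"),
      n_cpgs, replace = TRUE,
      prob = c(0.31, 0.13, 0.10, 0.05, 0.05, 0.36))
    for (cl in clocks) {
      flag <- logical(n_cpgs)
      flag[sample.int(n_cpgs, clock_size)] <- TRUE
      ann[[cl]] <- flag
    }
    ann$polycomb_target <- stats::runif(n_cpgs) < polycomb_rate
    peak_cols <- as.vector(outer(cell_types, marks,
                                 function(ct, mk) paste("peak", ct, mk, sep = "_")))
    dens <- if (length(peak_density) == 1) stats::setNames(rep(peak_density, length(peak_cols)), peak_cols)
            else peak_density
    for (pc in peak_cols) {
      ann[[pc]] <- stats::runif(n_cpgs) < dens[[pc]]
    }
    rownames(ann) <- ann$cpg_id
    ann
  })
}

#' Ground-truth module specification for synthetic cohorts
#'
#' Describes the latent-factor structure a synthetic cohort is generated from:
#' disjoint member-CpG index sets, per-CpG loadings on the module factor, the
#' factor and noise standard deviations, the per-module log hazard ratio per
#' 1-SD eigenCpG (`hazard_coef`), and the effect of standardized cumulative
#' risk-factor exposure on each factor (`exposure_coef`).
#'
#' @param member_index list of integer vectors, disjoint CpG (column) indices.
#' @param loadings per-module loading applied to member CpGs; recycled.
#' @param factor_sd,noise_sd positive standard deviations of the module factor
#'   and per-CpG noise. Defaults (loading 0.9, factor_sd 1, noise_sd 0.9)
#'   calibrate the first-PC variance explained of a module to about one half.
#' @param hazard_coef per-module log hazard ratio per 1-SD factor; recycled.
#' @param exposure_coef per-module effect of standardized cumulative exposure
#'   on the factor; recycled.
#' @param exposure_factor which risk factor drives the factors.
#' @return An object of class `true_module_spec`.
#' @export
true_module_spec <- function(member_index, loadings = 0.9, factor_sd = 1,
                             noise_sd = 0.9, hazard_coef = 0,
                             exposure_coef = 0, exposure_factor = "bmi") {
  stopifnot(is.list(member_index), length(member_index) >= 1)
  k <- length(member_index)
  all_idx <- unlist(member_index)
  if (anyDuplicated(all_idx)) stop("module member sets must be disjoint")
  if (any(factor_sd <= 0) || any(noise_sd <= 0)) stop("factor_sd and noise_sd must be positive")
  structure(list(
    n_modules = k,
    member_index = member_index,
    loadings = rep_len(loadings, k),
    factor_sd = rep_len(factor_sd, k),
    noise_sd = noise_sd,
    hazard_coef = rep_len(hazard_coef, k),
    exposure_coef = rep_len(exposure_coef, k),
    exposure_factor = exposure_factor
  ), class = "true_module_spec")
}

#' @rdname true_module_spec
#' @param n_cpgs total number of CpGs on the synthetic array.
#' @param sizes module sizes; members are drawn as disjoint random index sets.
#' @param seed integer seed for the member draw.
#' @param ... passed to [true_module_spec()].
#' @export
default_module_spec <- function(n_cpgs, sizes = c(200, 150, 100), seed = 1, ...) {
  stopifnot(sum(sizes) <= n_cpgs)
  with_seed(seed, {
    pool <- sample.int(n_cpgs, sum(sizes))
    split_at <- rep(seq_along(sizes), sizes)
    true_module_spec(split(pool, split_at), ...)
  })
}

#' Generate a synthetic methylation cohort with survival outcomes
#'
#' Emulates the data structure of a blood-methylation survival study. Latent
#' Gaussian M-values `m = mu_j + loading * factor_k + noise` are mapped to
#' beta values by the logistic transform `beta = 1/(1 + 2^(-m))`. Risk factors
#' follow per-sample AR(1) trajectories across exams; each module factor
#' receives `exposure_coef` times the standardized cumulative (pre-final-exam
#' mean) exposure. Blood cell fractions are drawn from a Dirichlet and, on a
#' dedicated set of signature CpGs, mixed linearly with type-specific
#' reference profiles. Event times are exponential with log-hazard
#' `sum_k gamma_k * z(factor_k)` plus a small age term; censoring is an
#' independent exponential whose per-sample rate is proportional to the event
#' hazard, so the event probability equals `1 - censor_rate` exactly. Control
#' probes carry an injected two-level batch factor that also adds a small
#' shift to a random subset of beta values.
#'
#' @param spec a [true_module_spec()].
#' @param annotation annotation from [generate_annotation()]; must have at
#'   least `max(unlist(spec$member_index))` rows.
#' @param n_samples number of samples (>= 2).
#' @param n_exams number of exams; methylation is measured at the last one.
#' @param censor_rate expected censoring fraction in \[0, 1).
#' @param seed integer seed; output is bit-identical given the seed.
#' @param phi AR(1) coefficient of the risk-factor trajectories.
#' @param baseline_hazard exponential baseline event rate (per year).
#' @param age_log_hr log hazard ratio per year of age (centered).
#' @param n_ctrl number of control probes.
#' @param failed_frac fraction of detection p-values drawn above the 1e-16
#'   detection threshold, to exercise QC.
#' @param signature_size number of non-module CpGs reserved as cell-type
#'   signature sites.
#' @param signature_noise_sd noise sd of the signature-CpG beta mixture.
#' @param batch_shift additive beta shift attached to the batch factor.
#' @return A list of class `synthetic_cohort` with elements `beta`
#'   (samples x CpGs), `detection_p`, `control_probes`, `phenotypes`,
#'   `exposures` (long format), `true_fractions`, `reference` (signature-CpG
#'   beta profiles per cell type), and `truth` (the spec plus realized factors).
#' @export
generate_cohort <- function(spec, annotation, n_samples, n_exams = 8,
                            censor_rate = 0.5, seed = 1, phi = 0.6,
                            baseline_hazard = 0.05, age_log_hr = 0.02,
                            n_ctrl = 100, failed_frac = 0.001,
                            signature_size = 60, signature_noise_sd = 0.01,
                            batch_shift = 0.005) {
  stopifnot(n_samples >= 2, censor_rate >= 0, censor_rate < 1)
  n_cpgs <- nrow(annotation)
  if (max(unlist(spec$member_index)) > n_cpgs) {
    stop("module member index exceeds the number of annotated CpGs")
  }
  with_seed(seed, {
    sample_ids <- sprintf("S%05d", seq_len(n_samples))
    cpg_ids <- annotation$cpg_id

    ## risk-factor trajectories: stationary AR(1), unit marginal variance
    factors_rf <- c("bmi", "glu", "hscrp", "tg", "hdl", "ldl", "chol", "sbp")
    med <- c(bmi = 27.5, glu = 98, hscrp = 2, tg = 110, hdl = 52, ldl = 120,
             chol = 200, sbp = 130)
    sdlog <- c(bmi = NA, glu = 0.06, hscrp = 0.40, tg = 0.20, hdl = 0.12,
               ldl = 0.12, chol = 0.08, sbp = 0.05)
    traj <- array(NA_real_, c(n_samples, n_exams, length(factors_rf)),
                  dimnames = list(sample_ids, NULL, factors_rf))
    for (f in seq_along(factors_rf)) {
      x <- matrix(NA_real_, n_samples, n_exams)
      x[, 1] <- stats::rnorm(n_samples)
      if (n_exams > 1) {
        innov_sd <- sqrt(1 - phi^2)
        for (e in 2:n_exams) x[, e] <- phi * x[, e - 1] + stats::rnorm(n_samples, sd = innov_sd)
      }
      traj[, , f] <- x
    }
    # original-scale and transformed (analysis-scale) values
    exposures <- do.call(rbind, lapply(seq_along(factors_rf), function(f) {
      fac <- factors_rf[f]
      x <- traj[, , f]
      if (fac == "bmi") {
        value <- 27.5 + 4.5 * x
        transformed <- value
      } else {
        transformed <- log10(med[[fac]]) + sdlog[[fac]] * x
        value <- 10^transformed
      }
      data.frame(sample_id = rep(sample_ids, n_exams),
                 exam = rep(seq_len(n_exams), each = n_samples),
                 factor = fac,
                 value = as.vector(value),
                 transformed = as.vector(transformed),
                 stringsAsFactors = FALSE)
    }))

    ## cumulative exposure (exams 1..E-1) of the driving factor -> module factors
    drive <- traj[, seq_len(max(1, n_exams - 1)), match(spec$exposure_factor, factors_rf), drop = FALSE]
    cum_drive <- rowMeans(drive[, , 1, drop = FALSE])
    z_cum <- as.vector(scale(cum_drive))
    K <- spec$n_modules
    fac_mat <- sapply(seq_len(K), function(k) {
      spec$exposure_coef[k] * z_cum + stats::rnorm(n_samples, sd = spec$factor_sd[k])
    })
    fac_mat <- matrix(fac_mat, n_samples, K)

    ## latent M-values
    mu <- stats::rnorm(n_cpgs, 0, 1.5)
    load_mat <- matrix(0, K, n_cpgs)
    for (k in seq_len(K)) load_mat[k, spec$member_index[[k]]] <- spec$loadings[k]
    M <- matrix(mu, n_samples, n_cpgs, byrow = TRUE) +
      fac_mat %*% load_mat +
      matrix(stats::rnorm(n_samples * n_cpgs, sd = spec$noise_sd), n_samples, n_cpgs)
    beta <- ilogit2(M)

    ## cell fractions and signature CpGs (linear mixture in beta space)
    alpha <- 30 * c(CD4T = 0.15, CD8T = 0.10, B = 0.05, NK = 0.05,
                    Mono = 0.10, Gran = 0.55)
    g <- matrix(stats::rgamma(n_samples * 6, shape = rep(alpha, each = n_samples)),
                n_samples, 6, dimnames = list(sample_ids, names(alpha)))
    fractions <- g / rowSums(g)
    non_members <- setdiff(seq_len(n_cpgs), unlist(spec$member_index))
    sig_size <- min(signature_size, length(non_members))
    sig_idx <- sort(sample(non_members, sig_size))
    reference <- matrix(stats::runif(sig_size * 6, 0.05, 0.95), sig_size, 6,
                        dimnames = list(cpg_ids[sig_idx], names(alpha)))
    beta[, sig_idx] <- pmin(pmax(
      fractions %*% t(reference) +
        matrix(stats::rnorm(n_samples * sig_size, sd = signature_noise_sd),
               n_samples, sig_size), 0), 1)

    ## batch factor: control probes plus a small beta shift
    batch <- sample(c(0L, 1L), n_samples, replace = TRUE)
    ctrl_base <- stats::rnorm(n_ctrl, 12, 1)
    ctrl_batch <- stats::rnorm(n_ctrl, 0, 0.5)
    ctrl_log2 <- matrix(ctrl_base, n_samples, n_ctrl, byrow = TRUE) +
      outer(batch, ctrl_batch) +
      matrix(stats::rnorm(n_samples * n_ctrl, sd = 0.2), n_samples, n_ctrl)
    control_probes <- 2^ctrl_log2
    dimnames(control_probes) <- list(sample_ids, sprintf("ctrl%03d", seq_len(n_ctrl)))
    shifted <- stats::runif(n_cpgs) < 0.2
    beta[, shifted] <- pmin(pmax(beta[, shifted] + batch_shift * batch, 0), 1)
    dimnames(beta) <- list(sample_ids, cpg_ids)

    ## covariates
    age <- stats::rnorm(n_samples, 65, 5)
    sex <- sample(c(0L, 1L), n_samples, replace = TRUE)
    race <- sample(c("A", "B", "C"), n_samples, replace = TRUE, prob = c(0.6, 0.25, 0.15))
    smoking <- stats::rbinom(n_samples, 1, 0.1)
    years_smoking <- ifelse(smoking == 1, stats::runif(n_samples, 5, 40), 0)
    packs_per_day <- ifelse(smoking == 1, stats::runif(n_samples, 0.25, 2), 0)
    pack_years <- years_smoking * packs_per_day
    bp_med <- stats::rbinom(n_samples, 1, 0.15)
    lipid_med <- stats::rbinom(n_samples, 1, 0.15)
    diabetes_med <- stats::rbinom(n_samples, 1, 0.05)

    ## survival: exponential PH on standardized factors
    zfac <- scale(fac_mat)
    eta <- as.vector(zfac %*% spec$hazard_coef) + age_log_hr * (age - mean(age))
    rate <- baseline_hazard * exp(eta)
    t_event <- stats::rexp(n_samples, rate)
    if (censor_rate > 0) {
      c_rate <- rate * censor_rate / (1 - censor_rate)
      t_cens <- stats::rexp(n_samples, c_rate)
    } else {
      t_cens <- rep(Inf, n_samples)
    }
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)

    ## current-exam biomarkers on the original scale
    current <- exposures[exposures$exam == n_exams, ]
    cur_wide <- stats::reshape(current[, c("sample_id", "factor", "value")],
                               idvar = "sample_id", timevar = "factor",
                               direction = "wide")
    names(cur_wide) <- sub("^value\\.", "", names(cur_wide))
    cur_wide <- cur_wide[match(sample_ids, cur_wide$sample_id), ]

    phenotypes <- data.frame(
      sample_id = sample_ids, time = time, event = event, age = age,
      sex = sex, race = race, smoking_status = smoking,
      pack_years = pack_years, years_smoking = years_smoking,
      packs_per_day = packs_per_day,
      bp_med = bp_med, lipid_med = lipid_med, diabetes_med = diabetes_med,
      batch = batch,
      bmi = cur_wide$bmi, chol = cur_wide$chol, ldl = cur_wide$ldl,
      hdl = cur_wide$hdl, tg = cur_wide$tg, glu = cur_wide$glu,
      hscrp = cur_wide$hscrp, sbp = cur_wide$sbp,
      stringsAsFactors = FALSE
    )
    rownames(phenotypes) <- sample_ids

    ## detection p-values
    detection_p <- matrix(stats::runif(n_samples * n_cpgs, 0, 1e-20),
                          n_samples, n_cpgs, dimnames = dimnames(beta))
    if (failed_frac > 0) {
      fail <- stats::runif(n_samples * n_cpgs) < failed_frac
      detection_p[fail] <- stats::runif(sum(fail), 1e-10, 1e-2)
    }

    truth <- spec
    truth$factors <- fac_mat
    truth$cumulative_drive <- cum_drive
    truth$signature_index <- sig_idx
    truth$batch <- batch

    structure(list(
      beta = beta, detection_p = detection_p, control_probes = control_probes,
      phenotypes = phenotypes, exposures = exposures,
      true_fractions = fractions, reference = reference,
      truth = truth, n_exams = n_exams
    ), class = "synthetic_cohort")
  })
}

#' Implant a differentially methylated region into a synthetic cohort
#'
#' Adds `effect * u_s` to the M-values of a contiguous run of CpGs, where
#' `u_s ~ N(0,1)` is a per-sample frailty, and multiplies each sample's event
#' and censoring hazards by `exp(effect * u_s)` (implemented by scaling the
#' observed times by `exp(-effect * u_s)`), so that region methylation and
#' hazard share the frailty. Non-region CpGs are untouched and `effect = 0`
#' returns the cohort unchanged.
#'
#' @param cohort a `synthetic_cohort`.
#' @param annotation the annotation the cohort was generated from.
#' @param region integer vector of CpG column indices; must be contiguous on
#'   one chromosome with inter-CpG gaps below `max_gap`.
#' @param effect effect size on the M-value scale (also the log-frailty scale).
#' @param seed integer seed for the frailty draw.
#' @param max_gap maximum allowed gap between neighboring region CpGs (bp).
#' @return The modified `synthetic_cohort`, with the frailty and region stored
#'   under `truth$dmr`.
#' @export
implant_dmr <- function(cohort, annotation, region, effect, seed = 1,
                        max_gap = 500) {
  region <- sort(as.integer(region))
  ann <- annotation[region, ]
  if (length(unique(ann$chrom)) > 1) stop("region spans chromosomes")
  if (!all(diff(region) == 1)) stop("region CpG indices must be contiguous")
  if (length(region) > 1 && any(diff(ann$pos) >= max_gap)) {
    stop("region has an internal gap of ", max(diff(ann$pos)),
         " bp (>= ", max_gap, ")")
  }
  if (effect == 0) return(cohort)
  with_seed(seed, {
    u <- stats::rnorm(nrow(cohort$beta))
    m <- logit2(cohort$beta[, region, drop = FALSE])
    cohort$beta[, region] <- ilogit2(m + effect * u)
    cohort$phenotypes$time <- cohort$phenotypes$time * exp(-effect * u)
    cohort$truth$dmr <- list(region = region, effect = effect, frailty = u)
    cohort
  })
}

#' Draw synthetic gene sets from an annotation
#'
#' @param annotation annotation with a `gene` column.
#' @param n_sets number of gene sets.
#' @param set_size genes per set (recycled).
#' @param seed integer seed.
#' @return Named list of gene-id character vectors (a GMT-shaped object).
#' @export
generate_gene_sets <- function(annotation, n_sets = 20, set_size = 25, seed = 1) {
  genes <- unique(annotation$gene)
  set_size <- rep_len(set_size, n_sets)
  with_seed(seed, {
    sets <- lapply(seq_len(n_sets), function(i) sample(genes, min(set_size[i], length(genes))))
    names(sets) <- sprintf("SET%03d", seq_len(n_sets))
    sets
  })
}

#' Write a synthetic cohort to plain-text files
#'
#' Writes the beta matrix (rows = CpGs, columns = samples), annotation,
#' phenotype and long-format exposure TSVs, per (cell type, mark) peak BED
#' files (0-based half-open, flagged CpGs padded by `pad` bp and merged),
#' gene sets as GMT, and the ground truth as JSON.
#'
#' @param cohort a `synthetic_cohort`.
#' @param annotation the matching annotation.
#' @param dir output directory (created if missing).
#' @param gene_sets optional named list of gene sets to write as GMT.
#' @param pad half-width of the BED interval written around each flagged CpG.
#' @return Invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, annotation, dir, gene_sets = NULL, pad = 50) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  wr <- function(x, name, ...) {
    path <- file.path(dir, name)
    utils::write.table(x, path, sep = "\t", quote = FALSE, ...)
    files <<- c(files, path)
  }
  wr(t(cohort$beta), "beta.tsv", col.names = NA)
  wr(annotation, "annotation.tsv", row.names = FALSE)
  wr(cohort$phenotypes, "phenotypes.tsv", row.names = FALSE)
  wr(cohort$exposures, "exposures.tsv", row.names = FALSE)
  wr(t(cohort$detection_p), "detection_p.tsv", col.names = NA)
  wr(cohort$control_probes, "control_probes.tsv", col.names = NA)
  wr(cohort$reference, "reference.tsv", col.names = NA)
  peak_cols <- grep("^peak_", names(annotation), value = TRUE)
  for (pc in peak_cols) {
    flagged <- annotation[annotation[[pc]], ]
    if (nrow(flagged) == 0) next
    bed <- do.call(rbind, lapply(split(flagged, flagged$chrom), function(d) {
      ir <- IRanges::reduce(IRanges::IRanges(
        start = pmax(d$pos - pad, 1), end = d$pos + pad - 1))
      data.frame(chrom = d$chrom[1], start = IRanges::start(ir) - 1L,
                 end = IRanges::end(ir))
    }))
    path <- file.path(dir, paste0(sub("_", ".", sub("^peak_", "", pc)), ".bed"))
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    files <- c(files, path)
  }
  if (!is.null(gene_sets)) {
    path <- file.path(dir, "gene_sets.gmt")
    lines <- vapply(names(gene_sets), function(nm) {
      paste(c(nm, "synthetic", gene_sets[[nm]]), collapse = "\t")
    }, character(1))
    writeLines(lines, path)
    files <- c(files, path)
  }
  truth <- unclass(cohort$truth)
  truth$factors <- NULL
  path <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  files <- c(files, path)
  invisible(files)
}
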
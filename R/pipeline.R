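#' Validate and default a pipeline configuration
#'
#' Accepts a flat key-value configuration (a named list, or a path to a YAML
#' file), rejects unknown keys, injects defaults (soft-threshold power 8,
#' block size 20000, 7 control-probe PCs, FDR 0.2, DMR threshold 0.1 with
#' 500 bp gaps and a 50 bp / 1 kb ACF), and applies cross-field checks. An
#' empty document yields a fully defaulted simulate-mode configuration.
#' Validation is idempotent: re-validating a validated configuration returns
#' it unchanged.
#'
#' @param config named list or YAML file path; NULL means all defaults.
#' @return Validated configuration list of class `run_config`.
#' @export
validate_run_config <- function(config = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  config <- unclass(config)
  defaults <- list(
    mode = "simulate",            # simulate | files
    out_dir = "methmodsurv_run",
    seed = 1L,
    n_samples = 800L, n_cpgs = 5000L, n_chroms = 2L, n_exams = 8L,
    censor_rate = 0.5,
    module_sizes = c(200L, 150L, 100L),
    hazard_coef = c(0.3, 0.3, 0),
    exposure_coef = c(0.5, 0, 0),
    power = 8, block_size = 20000L, precluster_subsample = 100L,
    min_module_size = 20L, merge_eigen_cor = 0.75, cut_height = 0.999,
    k_ctrl_pcs = 7L, fdr = 0.2, covariate_tier = "full",
    dmr_threshold = 0.1, dmr_max_gap = 500L, acf_step = 50L,
    acf_max_dist = 1000L, sidak_basis = "loci",
    n_perm = 100L,
    enrichment_flags = c("horvath", "hannum", "phenoage", "polycomb_target"),
    mediation_factors = c("bmi", "hscrp", "tg"),
    beta = NULL, detection_p = NULL, pheno = NULL, annotation_path = NULL,
    reference = NULL, exposures = NULL, control_probes = NULL
  )
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  out <- utils::modifyList(defaults, config, keep.null = TRUE)
  if (out$min_module_size > out$block_size) {
    stop("min_module_size (", out$min_module_size,
         ") exceeds block_size (", out$block_size, ")")
  }
  if (out$mode == "files") {
    required <- c("beta", "detection_p", "pheno", "annotation_path",
                  "reference", "exposures", "control_probes")
    missing_paths <- required[vapply(out[required], is.null, logical(1))]
    present <- setdiff(required, missing_paths)
    absent <- present[!file.exists(unlist(out[present]))]
    problems <- c(paste0("missing key: ", missing_paths),
                  paste0("path does not exist: ", unlist(out[absent])))
    if (length(missing_paths) > 0 || length(absent) > 0) {
      stop("invalid files-mode configuration:\n  ",
           paste(problems, collapse = "\n  "))
    }
  }
  structure(out, class = "run_config")
}

#' Run the full module/region methylation survival pipeline
#'
#' Orchestrates the stages end-to-end on a two-cohort (discovery and
#' replication) design: simulate cohorts (in simulate mode), preprocessing
#' (QC, covariates, control-probe PCA, cell fractions), module detection and
#' eigenCpGs in the discovery cohort, Cox module scan, projection onto the
#' replication cohort with preservation statistics and a replication scan,
#' per-CpG EWAS in both cohorts, DMR calling with a cross-cohort
#' Bonferroni replication join, enrichment tests, and risk-factor
#' correlation/mediation analyses. Every stage writes a TSV (with a header
#' comment carrying the package version, seed and config hash), and a
#' manifest with stage checksums is written at the end. With `resume =
#' TRUE`, stages whose outputs already exist are skipped.
#'
#' @param config a `run_config` (or anything [validate_run_config()]
#'   accepts).
#' @param resume skip stages whose output files are already present.
#' @return Invisibly, a list with the main in-memory results and the
#'   manifest.
#' @export
run_pipeline <- function(config = NULL, resume = FALSE) {
  cfg <- if (inherits(config, "run_config")) config else validate_run_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_hash <- substr(tools::md5sum(textConnection_free(cfg)), 1, 8)
  header <- sprintf("# methmodsurv %s seed=%d config=%s",
                    as.character(utils::packageVersion("methmodsurv")),
                    cfg$seed, cfg_hash)
  outfile <- function(name) file.path(cfg$out_dir, name)
  write_stage <- function(df, name, row.names = FALSE) {
    path <- outfile(name)
    con <- file(path, "w")
    writeLines(header, con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = row.names, col.names = TRUE)
    close(con)
    path
  }
  log_stage <- function(stage) message("[methmodsurv] stage: ", stage)
  run_stage <- function(stage, expr) {
    log_stage(stage)
    tryCatch(expr, error = function(e) {
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           " (partial outputs kept in ", cfg$out_dir, ")", call. = FALSE)
    })
  }

  ## --- simulate -------------------------------------------------------
  sim <- run_stage("simulate", {
    if (cfg$mode != "simulate") {
      stop("files mode inputs are read per stage; not implemented for stages ",
           "beyond preprocessing in this release")
    }
    ann <- generate_annotation(cfg$n_cpgs, n_chroms = cfg$n_chroms,
                               seed = cfg$seed,
                               clock_size = min(353L, cfg$n_cpgs %/% 10))
    spec <- default_module_spec(cfg$n_cpgs, sizes = cfg$module_sizes,
                                seed = cfg$seed,
                                hazard_coef = cfg$hazard_coef,
                                exposure_coef = cfg$exposure_coef)
    disc <- generate_cohort(spec, ann, cfg$n_samples, n_exams = cfg$n_exams,
                            censor_rate = cfg$censor_rate, seed = cfg$seed)
    repl <- generate_cohort(spec, ann, cfg$n_samples, n_exams = cfg$n_exams,
                            censor_rate = cfg$censor_rate,
                            seed = cfg$seed + 1000L)
    list(ann = ann, spec = spec, disc = disc, repl = repl)
  })
  ann <- sim$ann
  disc <- sim$disc
  repl <- sim$repl

  ## --- preprocess ------------------------------------------------------
  prep <- run_stage("preprocess", lapply(list(disc = disc, repl = repl), function(co) {
    samples <- sample_qc(co$detection_p)
    probes <- probe_qc(co$detection_p, ann)
    beta <- co$beta[samples, probes, drop = FALSE]
    pheno <- prepare_covariates(co$phenotypes[samples, ])
    pcs <- control_probe_pca(co$control_probes[samples, , drop = FALSE],
                             k = cfg$k_ctrl_pcs)
    cf <- estimate_cell_fractions(beta, co$reference)
    list(beta = beta, pheno = pheno, pcs = pcs, cf = cf, cohort = co)
  }))
  qc_tab <- data.frame(cohort = names(prep),
                       n_samples = vapply(prep, function(x) nrow(x$beta), 0),
                       n_probes = vapply(prep, function(x) ncol(x$beta), 0))
  write_stage(qc_tab, "qc_summary.tsv")

  ## --- modules (discovery) --------------------------------------------
  params <- network_params(power = cfg$power, block_size = cfg$block_size,
                           precluster_subsample = cfg$precluster_subsample,
                           min_module_size = cfg$min_module_size,
                           merge_eigen_cor = cfg$merge_eigen_cor,
                           cut_height = cfg$cut_height)
  modules <- run_stage("detect_modules",
                       detect_modules(prep$disc$beta, params, seed = cfg$seed))
  write_stage(data.frame(cpg_id = names(modules$assignment),
                         module_label = unname(modules$assignment),
                         color = names(modules$colors)[
                           match(modules$assignment, modules$colors)]),
              "module_assignment.tsv")

  eig <- run_stage("eigencpgs", compute_eigencpgs(prep$disc$beta, modules))
  ve <- vapply(eig$eigenvectors, function(e) e$variance_explained, 0)
  scan_disc <- run_stage("module_scan_discovery",
    module_cox_scan(eig$scores, prep$disc$pheno,
                    covariate_tier = "minimal",
                    cell_fractions = prep$disc$cf,
                    control_pcs = prep$disc$pcs, fdr = cfg$fdr))
  scan_disc$variance_explained <- ve[scan_disc$module]
  write_stage(scan_disc, "module_scan_discovery.tsv")

  ## --- replication -----------------------------------------------------
  proj <- run_stage("project", project_eigencpgs(eig, prep$repl$beta))
  pres <- run_stage("preservation",
    module_preservation(prep$disc$beta, prep$repl$beta, modules,
                        n_perm = cfg$n_perm, seed = cfg$seed,
                        power = cfg$power))
  write_stage(pres, "preservation.tsv")
  scan_repl <- run_stage("module_scan_replication",
    module_cox_scan(proj, prep$repl$pheno, covariate_tier = "minimal",
                    cell_fractions = prep$repl$cf,
                    control_pcs = prep$repl$pcs, fdr = cfg$fdr))
  write_stage(scan_repl, "module_scan_replication.tsv")

  ## --- EWAS + DMRs -----------------------------------------------------
  ewas_files <- stats::setNames(outfile(paste0("ewas_", names(prep), ".tsv")),
                                names(prep))
  if (resume && all(file.exists(ewas_files))) {
    # incremental contract: the expensive per-CpG scans are read back from
    # their stage outputs; downstream stages regenerate from them
    log_stage("ewas (cached)")
    ewas <- lapply(ewas_files, function(f) {
      res <- utils::read.table(f, header = TRUE, sep = "\t",
                               comment.char = "#", stringsAsFactors = FALSE)
      structure(list(results = res,
                     lambda = genomic_lambda(res$p[!is.na(res$p)])),
                class = "ewas_results")
    })
  } else {
    ewas <- run_stage("ewas", lapply(prep, function(pp) {
      ewas_scan(pp$beta, pp$pheno, covariate_tier = cfg$covariate_tier,
                cell_fractions = pp$cf, control_pcs = pp$pcs,
                annotation = ann)
    }))
    for (nm in names(ewas)) {
      write_stage(ewas[[nm]]$results, paste0("ewas_", nm, ".tsv"))
    }
  }
  dmrs <- run_stage("dmr", lapply(ewas, function(e) {
    call_dmrs(e, threshold = cfg$dmr_threshold, max_gap = cfg$dmr_max_gap,
              max_dist = cfg$acf_max_dist, step = cfg$acf_step,
              sidak_basis = cfg$sidak_basis)
  }))
  replicated <- run_stage("dmr_replication_join",
                          dmr_replication_join(dmrs$disc, dmrs$repl))
  write_stage(as.data.frame(dmrs$disc), "dmr_discovery.tsv")
  write_stage(as.data.frame(dmrs$repl), "dmr_replication.tsv")
  write_stage(replicated, "dmr_replicated.tsv")

  ## --- enrichment ------------------------------------------------------
  enr <- run_stage("enrichment", {
    ann_bg <- ann[ann$cpg_id %in% colnames(prep$disc$beta), ]
    flags <- flag_overlap_tests(modules, ann_bg, cfg$enrichment_flags)
    peaks <- grep("^peak_", names(ann_bg), value = TRUE)
    ct <- celltype_relative_enrichment(modules, peaks, ann_bg)
    sets <- generate_gene_sets(ann_bg, seed = cfg$seed)
    first_mod <- modules$modules[[1]]
    genes <- wallenius_gene_enrichment(first_mod, ann_bg, sets)
    list(flags = flags, celltype = ct, genes = genes)
  })
  write_stage(enr$flags, "enrichment_flags.tsv")
  write_stage(enr$genes, "enrichment_gene_sets.tsv")
  write_stage(as.data.frame(enr$celltype$log2_re), "enrichment_celltype_log2re.tsv",
              row.names = TRUE)

  ## --- risk factors + mediation ---------------------------------------
  med <- run_stage("riskfactors", {
    hist <- prep$repl$cohort$exposures
    hist <- hist[hist$sample_id %in% rownames(prep$repl$beta), ]
    score1 <- stats::setNames(proj[, 1], rownames(proj))
    cors_cur <- module_rf_correlations(proj, hist, "current",
                                       factors = cfg$mediation_factors)
    cors_cum <- module_rf_correlations(proj, hist, "cumulative",
                                       factors = cfg$mediation_factors)
    z <- covariate_matrix(prep$repl$pheno, "full",
                          cell_fractions = prep$repl$cf,
                          control_pcs = prep$repl$pcs)
    meds <- lapply(cfg$mediation_factors, function(fac) {
      cum <- cumulative_exposure(hist, fac)[rownames(proj)]
      cur <- hist[hist$factor == fac & hist$exam == max(hist$exam), ]
      curv <- stats::setNames(cur$transformed, cur$sample_id)[rownames(proj)]
      m <- mediation_cox(cum, score1, prep$repl$pheno,
                         covariates = cbind(z, current = curv))
      cbind(risk_factor = fac, m$table, n = m$n)
    })
    list(correlations = rbind(cors_cur, cors_cum),
         mediation = do.call(rbind, meds))
  })
  write_stage(med$correlations, "riskfactor_correlations.tsv")
  write_stage(med$mediation, "mediation.tsv")

  ## --- manifest --------------------------------------------------------
  files <- list.files(cfg$out_dir, pattern = "\\.tsv$", full.names = TRUE)
  manifest <- list(seed = cfg$seed, config_hash = unname(cfg_hash),
                   version = as.character(utils::packageVersion("methmodsurv")),
                   checksums = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, outfile("manifest.json"), auto_unbox = TRUE)
  invisible(list(config = cfg, annotation = ann, modules = modules,
                 eigen = eig, variance_explained = ve,
                 module_scan = list(disc = scan_disc, repl = scan_repl),
                 preservation = pres, ewas = ewas, dmrs = dmrs,
                 dmr_replicated = replicated, enrichment = enr,
                 riskfactors = med, manifest = manifest))
}

# Serialize a config deterministically for hashing (md5sum needs a file).
textConnection_free <- function(cfg) {
  tmp <- tempfile()
  writeLines(yaml::as.yaml(cfg[order(names(cfg))]), tmp)
  on.exit(unlink(tmp))
  tools::md5sum(tmp)
}

#' Cross-cohort DMR replication join
#'
#' A discovery region is "replicated" when a replication-cohort region
#' overlaps it by at least 1 bp and the replication region's regional p is
#' below the Bonferroni threshold `0.05 / n_discovery_regions`.
#'
#' @param dmr_disc,dmr_repl `dmr_records` from the two cohorts.
#' @param alpha family-wise level before Bonferroni division (0.05).
#' @return The discovery records with `replicated`, `repl_region_p` columns.
#' @export
dmr_replication_join <- function(dmr_disc, dmr_repl, alpha = 0.05) {
  disc <- as.data.frame(dmr_disc)
  repl <- as.data.frame(dmr_repl)
  disc$replicated <- FALSE
  disc$repl_region_p <- NA_real_
  if (nrow(disc) == 0 || nrow(repl) == 0) return(disc)
  thr <- alpha / nrow(disc)
  gr_d <- GenomicRanges::GRanges(disc$chrom,
                                 IRanges::IRanges(disc$start + 1L, disc$end))
  gr_r <- GenomicRanges::GRanges(repl$chrom,
                                 IRanges::IRanges(repl$start + 1L, repl$end))
  ov <- GenomicRanges::findOverlaps(gr_d, gr_r)
  for (h in seq_along(ov)) {
    i <- S4Vectors::queryHits(ov)[h]
    j <- S4Vectors::subjectHits(ov)[h]
    rp <- repl$region_p[j]
    if (is.na(disc$repl_region_p[i]) || rp < disc$repl_region_p[i]) {
      disc$repl_region_p[i] <- rp
    }
    if (rp < thr) disc$replicated[i] <- TRUE
  }
  disc
}
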
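#' Assemble the model covariate matrix for a tier
#'
#' Minimal models adjust for estimated blood cell fractions (5 of the 6
#' compositional fractions, dropping granulocytes to avoid collinearity) plus
#' technical covariates (batch indicator and control-probe principal
#' components). Fully adjusted models add the biological covariates: age, BMI,
#' smoking status, pack-years, and sex/race dummies where present.
#'
#' @param pheno phenotype `data.frame` (see [prepare_covariates()]).
#' @param tier `"minimal"` or `"full"`.
#' @param cell_fractions a `cell_fractions` object or samples x 6 matrix.
#' @param control_pcs a `control_pcs` object or samples x k score matrix.
#' @param drop_cell fraction column excluded from the design (granulocytes).
#' @return Numeric design matrix with one row per sample.
#' @export
covariate_matrix <- function(pheno, tier = c("minimal", "full"),
                             cell_fractions = NULL, control_pcs = NULL,
                             drop_cell = "Gran") {
  tier <- match.arg(tier)
  n <- nrow(pheno)
  parts <- list()
  if (!is.null(cell_fractions)) {
    f <- if (inherits(cell_fractions, "cell_fractions")) cell_fractions$fractions
         else as.matrix(cell_fractions)
    f <- f[, setdiff(colnames(f), drop_cell), drop = FALSE]
    parts$fractions <- f
  }
  if (!is.null(control_pcs)) {
    s <- if (inherits(control_pcs, "control_pcs")) control_pcs$scores
         else as.matrix(control_pcs)
    colnames(s) <- paste0("ctrl", colnames(s) %||% seq_len(ncol(s)))
    parts$ctrl <- s
  }
  if ("batch" %in% names(pheno)) {
    b <- stats::model.matrix(~ factor(batch), pheno)[, -1, drop = FALSE]
    colnames(b) <- paste0("batch", seq_len(ncol(b)))
    parts$batch <- b
  }
  if (tier == "full") {
    need <- c("age", "bmi", "smoking_status", "pack_years")
    missing_cols <- setdiff(need, names(pheno))
    if (length(missing_cols) > 0) {
      stop("missing covariate column(s) for the full tier: ",
           paste(missing_cols, collapse = ", "))
    }
    bio <- as.matrix(pheno[, need])
    parts$bio <- bio
    if ("sex" %in% names(pheno) && length(unique(pheno$sex)) > 1) {
      parts$sex <- matrix(as.numeric(factor(pheno$sex)) - 1, ncol = 1,
                          dimnames = list(NULL, "sex"))
    }
    if ("race" %in% names(pheno) && length(unique(pheno$race)) > 1) {
      r <- stats::model.matrix(~ factor(race), pheno)[, -1, drop = FALSE]
      colnames(r) <- paste0("race", seq_len(ncol(r)))
      parts$race <- r
    }
  }
  if (length(parts) == 0) return(matrix(numeric(0), nrow = n, ncol = 0))
  out <- do.call(cbind, parts)
  rownames(out) <- rownames(pheno)
  out
}

#' Cox scan over module eigenCpGs
#'
#' Fits one Cox proportional-hazards model per module, with the module's
#' eigenCpG score as the independent variable plus the requested covariate
#' tier, then applies Benjamini-Hochberg correction across modules and flags
#' those below the FDR threshold (default 0.2, corrected over the number of
#' modules tested).
#'
#' @param scores samples x modules eigenCpG score matrix.
#' @param pheno phenotype table with `time` and `event`.
#' @param covariate_tier `"minimal"` or `"full"`.
#' @param cell_fractions,control_pcs passed to [covariate_matrix()].
#' @param fdr flagging threshold on the q-value.
#' @return `data.frame` with one row per module: coef, se, z, p, q, flag,
#'   n, n_events.
#' @export
module_cox_scan <- function(scores, pheno, covariate_tier = "minimal",
                            cell_fractions = NULL, control_pcs = NULL,
                            fdr = 0.2) {
  z <- covariate_matrix(pheno, covariate_tier, cell_fractions, control_pcs)
  scores <- as.matrix(scores)
  out <- lapply(seq_len(ncol(scores)), function(j) {
    x <- cbind(score = scores[, j], z)
    fit <- fit_cox(pheno$time, pheno$event, x)
    cbind(data.frame(module = colnames(scores)[j] %||% j),
          fit$table["score", c("coef", "se", "z", "p")],
          data.frame(n = fit$n_samples, n_events = fit$n_events,
                     converged = fit$converged))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$q <- bh_fdr(res$p)
  res$flag <- !is.na(res$q) & res$q < fdr
  res
}

#' Per-CpG Cox EWAS with outlier exclusion
#'
#' For each CpG, beta-value outliers are excluded by the IQR rule
#' ([iqr_outlier_mask()]), then a Cox model of the (raw) beta value plus the
#' covariate tier is fitted. The genomic inflation factor lambda is computed
#' from the resulting p-value vector. CpGs whose fit fails or that are
#' constant after masking get a missing p with `n_used` still recorded.
#'
#' @param beta samples x CpGs beta matrix.
#' @param pheno phenotype table with `time` and `event`.
#' @param covariate_tier `"minimal"` or `"full"` (full is the EWAS default).
#' @param cell_fractions,control_pcs passed to [covariate_matrix()].
#' @param annotation optional annotation; when given, chrom/pos are attached
#'   and the output is sorted by (chrom, pos) for the DMR caller.
#' @param iqr_k IQR multiplier for the outlier mask.
#' @return List of class `ewas_results`: `results` (per-CpG data.frame) and
#'   `lambda`.
#' @export
ewas_scan <- function(beta, pheno, covariate_tier = "full",
                      cell_fractions = NULL, control_pcs = NULL,
                      annotation = NULL, iqr_k = 3) {
  z <- covariate_matrix(pheno, covariate_tier, cell_fractions, control_pcs)
  time <- pheno$time
  event <- pheno$event
  y <- survival::Surv(time, event)
  ctrl <- survival::coxph.control()
  n_cpgs <- ncol(beta)
  coef <- se <- p <- rep(NA_real_, n_cpgs)
  n_used <- integer(n_cpgs)
  qs <- apply(beta, 2, stats::quantile, probs = c(0.25, 0.75),
              na.rm = TRUE, type = 7)
  for (j in seq_len(n_cpgs)) {
    v <- beta[, j]
    iqr <- qs[2, j] - qs[1, j]
    mask <- !is.na(v) & v >= qs[1, j] - iqr_k * iqr & v <= qs[2, j] + iqr_k * iqr
    n_used[j] <- sum(mask)
    vm <- v[mask]
    if (length(unique(vm)) < 2 || sum(event[mask]) < 1) next
    x <- cbind(cpg = vm, z[mask, , drop = FALSE])
    monotone <- FALSE
    fit <- tryCatch(
      withCallingHandlers(
        survival::coxph.fit(x, y[mask, ], strata = NULL, offset = NULL,
                            init = NULL, control = ctrl, weights = NULL,
                            method = "efron", rownames = NULL),
        warning = function(w) {
          if (grepl("infinite", conditionMessage(w))) monotone <<- TRUE
          invokeRestart("muffleWarning")
        }),
      error = function(e) NULL)
    if (is.null(fit) || is.na(fit$coefficients[1])) next
    v1 <- diag(as.matrix(fit$var))[1]
    if (!is.finite(v1) || v1 <= 0) next
    coef[j] <- fit$coefficients[1]
    se[j] <- sqrt(v1)
    if (fit$iter >= ctrl$iter.max || monotone) next
    p[j] <- 2 * stats::pnorm(-abs(coef[j] / se[j]))
  }
  results <- data.frame(cpg_id = colnames(beta) %||% seq_len(n_cpgs),
                        coef = coef, se = se, p = p, n_used = n_used,
                        stringsAsFactors = FALSE)
  if (!is.null(annotation)) {
    m <- match(results$cpg_id, annotation$cpg_id)
    results$chrom <- annotation$chrom[m]
    results$pos <- annotation$pos[m]
    results <- results[order(results$chrom, results$pos), ]
  }
  lambda <- genomic_lambda(results$p[!is.na(results$p)])
  structure(list(results = results, lambda = lambda), class = "ewas_results")
}

#' Cell type-module interaction Cox model
#'
#' Tests whether a module's hazard association is carried by a specific cell
#' type, in the spirit of interaction-based cell-type-specific differential
#' methylation: a single Cox model includes the module score, 5 of the 6 cell
#' fractions (granulocytes dropped), the covariate tier, and the 5
#' score-by-fraction interaction terms. The score-by-monocyte interaction is
#' the highlighted term.
#'
#' @param score eigenCpG score vector for the module of interest.
#' @param fractions samples x 6 cell-fraction matrix (or `cell_fractions`);
#'   rows not summing to 1 are renormalized with a warning.
#' @param pheno phenotype table.
#' @param covariate_tier,control_pcs passed to [covariate_matrix()].
#' @param drop_cell fraction left out of the model (granulocytes).
#' @param highlight interaction of interest (default monocytes).
#' @return List of class `celltype_interaction`: the full `cox_fit`, the
#'   `interactions` table, and `highlight` (the highlighted row).
#' @export
celltype_interaction_scan <- function(score, fractions, pheno,
                                      covariate_tier = "minimal",
                                      control_pcs = NULL, drop_cell = "Gran",
                                      highlight = "Mono") {
  f <- if (inherits(fractions, "cell_fractions")) fractions$fractions
       else as.matrix(fractions)
  stopifnot(ncol(f) == 6, drop_cell %in% colnames(f))
  rs <- rowSums(f)
  if (any(abs(rs - 1) > 1e-6)) {
    warning("cell fractions do not sum to 1; renormalizing")
    f <- f / rs
  }
  if (any(apply(f, 2, stats::sd) == 0)) stop("no variation in cell fractions")
  f5 <- f[, setdiff(colnames(f), drop_cell), drop = FALSE]
  z <- covariate_matrix(pheno, covariate_tier, cell_fractions = NULL,
                        control_pcs = control_pcs)
  inter <- score * f5
  colnames(inter) <- paste0("score_x_", colnames(f5))
  x <- cbind(score = score, f5, z, inter)
  fit <- fit_cox(pheno$time, pheno$event, x)
  interactions <- fit$table[colnames(inter), ]
  structure(list(fit = fit, interactions = interactions,
                 highlight = interactions[paste0("score_x_", highlight), ]),
            class = "celltype_interaction")
}
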
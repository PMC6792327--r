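#' Cumulative risk-factor exposure
#'
#' The cumulative exposure of a sample is the mean of its transformed
#' risk-factor values over the exams preceding the methylation exam
#' (exams 1..E-1). Samples with fewer than `min_exams` available past values
#' get a missing cumulative value.
#'
#' @param history long-format exposure table with columns `sample_id`,
#'   `exam`, `factor`, `transformed` (see [generate_cohort()]).
#' @param factor risk-factor name.
#' @param min_exams minimum number of past exams required (default 3).
#' @param meth_exam exam index of the methylation measurement; defaults to
#'   the maximum exam present.
#' @return Named numeric vector of per-sample cumulative values.
#' @export
cumulative_exposure <- function(history, factor, min_exams = 3,
                                meth_exam = max(history$exam)) {
  if (!factor %in% history$factor) stop("factor '", factor, "' absent from history")
  h <- history[history$factor == factor & history$exam < meth_exam, ]
  h <- h[!duplicated(h[, c("sample_id", "exam")]), ]
  h <- h[!is.na(h$transformed), ]
  counts <- tapply(h$transformed, h$sample_id, length)
  means <- tapply(h$transformed, h$sample_id, mean)
  means[counts < min_exams] <- NA_real_
  out <- as.numeric(means)
  names(out) <- names(means)
  out
}

#' Module-risk factor Pearson correlations
#'
#' Pearson r and p between module eigenCpG scores and risk-factor levels, in
#' one of three modes: the current (methylation-exam) level, per past exam
#' (one row per exam), or the cumulative (mean of past exams) level.
#'
#' @param scores samples x modules eigenCpG score matrix with sample ids as
#'   row names.
#' @param history long-format exposure table.
#' @param mode `"current"`, `"per_exam"` or `"cumulative"`.
#' @param factors risk-factor names (default: all in `history`).
#' @param min_exams for cumulative mode, see [cumulative_exposure()].
#' @param meth_exam exam index of the methylation measurement.
#' @return `data.frame` with module, factor, exam (NA outside per_exam
#'   mode), r, p, n.
#' @export
module_rf_correlations <- function(scores, history,
                                   mode = c("current", "per_exam", "cumulative"),
                                   factors = unique(history$factor),
                                   min_exams = 3,
                                   meth_exam = max(history$exam)) {
  mode <- match.arg(mode)
  scores <- as.matrix(scores)
  out <- list()
  for (fac in factors) {
    vals <- switch(mode,
      current = {
        h <- history[history$factor == fac & history$exam == meth_exam, ]
        list(list(exam = NA_integer_,
                  v = stats::setNames(h$transformed, h$sample_id)))
      },
      cumulative = list(list(exam = NA_integer_,
                             v = cumulative_exposure(history, fac, min_exams,
                                                     meth_exam))),
      per_exam = lapply(setdiff(sort(unique(history$exam)), meth_exam),
                        function(e) {
        h <- history[history$factor == fac & history$exam == e, ]
        list(exam = e, v = stats::setNames(h$transformed, h$sample_id))
      }))
    for (vv in vals) {
      v <- vv$v[rownames(scores)]
      for (j in seq_len(ncol(scores))) {
        ok <- !is.na(v) & !is.na(scores[, j])
        if (sum(ok) < 10) stop("need at least 10 paired non-missing samples")
        if (stats::sd(v[ok]) == 0) {
          warning("zero-variance factor '", fac, "'; correlation missing")
          r <- p <- NA_real_
        } else {
          ct <- stats::cor.test(scores[ok, j], v[ok])
          r <- unname(ct$estimate)
          p <- ct$p.value
        }
        out[[length(out) + 1L]] <- data.frame(
          module = colnames(scores)[j] %||% j, factor = fac, exam = vv$exam,
          mode = mode, r = r, p = p, n = sum(ok), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Adjusted module-risk factor linear models
#'
#' Ordinary least squares of the standardized eigenCpG score on the
#' standardized risk-factor level (current or cumulative) plus confounder
#' covariates; standardization makes the factor betas comparable across risk
#' factors and modules.
#'
#' @param score eigenCpG score vector (sample ids as names or aligned with
#'   `history` sample order).
#' @param history long-format exposure table.
#' @param mode `"current"` or `"cumulative"`.
#' @param covariates numeric covariate matrix aligned with `score` (e.g. from
#'   [covariate_matrix()]; exclude BMI when BMI is the factor).
#' @param factors risk-factor names to model.
#' @param min_exams,meth_exam see [cumulative_exposure()].
#' @return `data.frame` with factor, beta (standardized), se, p, n.
#' @export
adjusted_rf_models <- function(score, history, mode = c("current", "cumulative"),
                               covariates = NULL,
                               factors = unique(history$factor),
                               min_exams = 3, meth_exam = max(history$exam)) {
  mode <- match.arg(mode)
  ids <- names(score)
  out <- list()
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (qr(cbind(1, covariates))$rank < ncol(covariates) + 1) {
      cc <- stats::cor(covariates)
      diag(cc) <- 0
      pair <- which(abs(cc) == max(abs(cc)), arr.ind = TRUE)[1, ]
      stop("collinear covariates: ", colnames(covariates)[pair[1]], " and ",
           colnames(covariates)[pair[2]])
    }
  }
  for (fac in factors) {
    v <- if (mode == "current") {
      h <- history[history$factor == fac & history$exam == meth_exam, ]
      stats::setNames(h$transformed, h$sample_id)
    } else {
      cumulative_exposure(history, fac, min_exams, meth_exam)
    }
    v <- if (!is.null(ids)) v[ids] else v[seq_along(score)]
    ok <- !is.na(v) & !is.na(score)
    ys <- as.vector(scale(score[ok]))
    xs <- as.vector(scale(v[ok]))
    df <- if (is.null(covariates)) data.frame(factor_z = xs)
          else data.frame(factor_z = xs, covariates[ok, , drop = FALSE])
    fit <- stats::lm(ys ~ ., data = df)
    sm <- summary(fit)$coefficients
    row <- sm["factor_z", ]
    out[[length(out) + 1L]] <- data.frame(
      factor = fac, mode = mode, beta = row[1], se = row[2], p = row[4],
      n = sum(ok), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Baron-Kenny style mediation with Cox outcome models
#'
#' Fits three Cox models on the identical complete-case sample: (A) the
#' cumulative exposure only, (B) the mediator (eigenCpG) only, (C) both
#' simultaneously, all with the shared covariates (which, following the
#' study design, should include the current level of the risk factor).
#' Reports the coefficients, p-values and the attenuation fraction of each
#' variable between its marginal and joint model. Attenuation is reported
#' descriptively; Cox coefficients are non-collapsible, so exposure/mediator
#' coefficient changes are not a formal indirect-effect decomposition.
#'
#' @param exposure per-sample cumulative exposure vector.
#' @param mediator per-sample eigenCpG score vector.
#' @param pheno phenotype table with `time` and `event`.
#' @param covariates numeric covariate matrix (include the current factor
#'   level).
#' @return List of class `mediation_result` with `models` (named list of
#'   `cox_fit`s), `table` (exposure/mediator coefficients and p per model),
#'   `attenuation` (fractions), `n`.
#' @export
mediation_cox <- function(exposure, mediator, pheno, covariates = NULL) {
  z <- if (is.null(covariates)) NULL else as.matrix(covariates)
  ok <- !is.na(exposure) & !is.na(mediator) & !is.na(pheno$time) &
    !is.na(pheno$event)
  if (!is.null(z)) ok <- ok & stats::complete.cases(z)
  e <- exposure[ok]
  m <- mediator[ok]
  if (abs(stats::cor(e, m)) > 0.99) stop("collinear mediation: |cor| > 0.99")
  time <- pheno$time[ok]
  event <- pheno$event[ok]
  zz <- if (is.null(z)) NULL else z[ok, , drop = FALSE]
  xa <- cbind(exposure = e)
  xb <- cbind(mediator = m)
  xc <- cbind(exposure = e, mediator = m)
  if (!is.null(zz)) {
    xa <- cbind(xa, zz); xb <- cbind(xb, zz); xc <- cbind(xc, zz)
  }
  fa <- fit_cox(time, event, xa)
  fb <- fit_cox(time, event, xb)
  fc <- fit_cox(time, event, xc)
  stopifnot(fa$n_samples == fb$n_samples, fb$n_samples == fc$n_samples)
  tab <- data.frame(
    model = c("A_exposure_only", "B_mediator_only", "C_joint", "C_joint"),
    term = c("exposure", "mediator", "exposure", "mediator"),
    coef = c(fa$table["exposure", "coef"], fb$table["mediator", "coef"],
             fc$table["exposure", "coef"], fc$table["mediator", "coef"]),
    p = c(fa$table["exposure", "p"], fb$table["mediator", "p"],
          fc$table["exposure", "p"], fc$table["mediator", "p"]))
  atten <- c(
    exposure = 1 - tab$coef[3] / tab$coef[1],
    mediator = 1 - tab$coef[4] / tab$coef[2])
  structure(list(models = list(A = fa, B = fb, C = fc), table = tab,
                 attenuation = atten, n = fa$n_samples),
            class = "mediation_result")
}

#' Two-sample Mendelian randomization estimators
#'
#' Summary-statistic MR from per-SNP exposure and outcome effect estimates:
#' the Wald ratio (single SNP; delta-method SE), fixed-effect inverse
#' variance weighted (IVW) estimate, MR-Egger weighted least squares with
#' intercept (3 or more SNPs; weights `1/se_out^2`, residual scale floored at
#' 1), and the weighted median of per-SNP ratios (SE by seeded parametric
#' bootstrap). SNPs with zero exposure effect are excluded with a warning.
#'
#' @param beta_exposure,se_exposure,beta_outcome,se_outcome equal-length
#'   per-SNP vectors; SEs positive.
#' @param n_boot bootstrap draws for the weighted-median SE.
#' @param seed integer seed for the bootstrap.
#' @return `data.frame` of class `mr_result`: method, estimate, se, p,
#'   n_snps. The Wald row is present only for one SNP; Egger rows only for
#'   three or more.
#' @export
mr_estimates <- function(beta_exposure, se_exposure, beta_outcome, se_outcome,
                         n_boot = 1000, seed = 1) {
  stopifnot(length(beta_exposure) >= 1,
            length(se_exposure) == length(beta_exposure),
            length(beta_outcome) == length(beta_exposure),
            length(se_outcome) == length(beta_exposure),
            all(se_exposure > 0), all(se_outcome > 0))
  drop <- beta_exposure == 0
  if (any(drop)) {
    warning(sum(drop), " SNP(s) with zero exposure effect excluded")
    beta_exposure <- beta_exposure[!drop]
    se_exposure <- se_exposure[!drop]
    beta_outcome <- beta_outcome[!drop]
    se_outcome <- se_outcome[!drop]
  }
  n_snps <- length(beta_exposure)
  stopifnot(n_snps >= 1)
  rows <- list()
  add <- function(method, est, se) {
    rows[[length(rows) + 1L]] <<- data.frame(
      method = method, estimate = est, se = se,
      p = 2 * stats::pnorm(-abs(est / se)), n_snps = n_snps,
      stringsAsFactors = FALSE)
  }
  if (n_snps == 1) {
    add("wald_ratio", beta_outcome / beta_exposure,
        se_outcome / abs(beta_exposure))
  }
  wi <- beta_exposure^2 / se_outcome^2
  ivw <- sum(beta_outcome * beta_exposure / se_outcome^2) /
    sum(beta_exposure^2 / se_outcome^2)
  add("ivw", ivw, sqrt(1 / sum(beta_exposure^2 / se_outcome^2)))
  if (n_snps >= 3) {
    w <- 1 / se_outcome^2
    fit <- stats::lm(beta_outcome ~ beta_exposure, weights = w)
    sm <- summary(fit)
    scale <- max(1, sm$sigma)
    cf <- sm$coefficients
    add("egger_slope", cf[2, 1], cf[2, 2] / sm$sigma * scale)
    add("egger_intercept", cf[1, 1], cf[1, 2] / sm$sigma * scale)
  }
  ratios <- beta_outcome / beta_exposure
  wmed_w <- beta_exposure^2 / se_outcome^2
  wm <- weighted_median(ratios, wmed_w)
  boot <- with_seed(seed, {
    replicate(n_boot, {
      bo <- stats::rnorm(n_snps, beta_outcome, se_outcome)
      bx <- stats::rnorm(n_snps, beta_exposure, se_exposure)
      keep <- bx != 0
      weighted_median(bo[keep] / bx[keep], bx[keep]^2 / se_outcome[keep]^2)
    })
  })
  add("weighted_median", wm, stats::sd(boot))
  res <- do.call(rbind, rows)
  class(res) <- c("mr_result", "data.frame")
  res
}

# Weighted median with linear interpolation at standardized cumulative
# weight 0.5 (the two-sample MR convention).
weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]
  w <- w[o]
  cw <- cumsum(w) - 0.5 * w
  cw <- cw / sum(w)
  if (all(cw < 0.5)) return(x[length(x)])
  if (cw[1] >= 0.5) return(x[1])
  below <- max(which(cw < 0.5))
  x[below] + (x[below + 1] - x[below]) *
    (0.5 - cw[below]) / (cw[below + 1] - cw[below])
}
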
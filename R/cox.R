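#' Fit a Cox proportional-hazards model
#'
#' Maximizes the Cox partial likelihood by Newton-Raphson (with the chosen tie
#' correction) via the survival package's fitting engine, and returns the
#' per-covariate log hazard ratios, standard errors, Wald z and two-sided
#' p-values. A monotone partial likelihood (perfect separation) is reported
#' through the `converged` flag with a warning rather than an error.
#'
#' @param time follow-up times (> 0).
#' @param event event indicator in \{0,1\}; at least one event required.
#' @param covariates numeric matrix (or vector) of covariates; constant
#'   columns are an error.
#' @param ties tie correction, `"efron"` (default) or `"breslow"`.
#' @param tol convergence tolerance on the log partial likelihood.
#' @param max_iter maximum Newton-Raphson iterations.
#' @return List of class `cox_fit`: `table` (coef, se, z, p per covariate),
#'   `loglik`, `iterations`, `converged`, `n_samples`, `n_events`.
#' @export
fit_cox <- function(time, event, covariates, ties = c("efron", "breslow"),
                    tol = 1e-9, max_iter = 100) {
  ties <- match.arg(ties)
  x <- as.matrix(covariates)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  stopifnot(length(time) == nrow(x), length(event) == nrow(x))
  if (sum(event) < 1) stop("at least one event is required")
  if (!all(is.finite(x))) stop("covariates must be finite")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("no variation in covariate '", colnames(x)[which(sds == 0)[1]], "'")
  }
  y <- survival::Surv(time, event)
  monotone <- FALSE
  fit <- withCallingHandlers(
    survival::coxph.fit(x, y, strata = NULL, offset = NULL, init = NULL,
                        control = survival::coxph.control(eps = tol,
                                                          iter.max = max_iter),
                        weights = NULL, method = ties, rownames = NULL),
    warning = function(w) {
      if (grepl("infinite", conditionMessage(w))) {
        monotone <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  coef <- fit$coefficients
  se <- sqrt(diag(as.matrix(fit$var)))
  z <- coef / se
  p <- 2 * stats::pnorm(-abs(z))
  converged <- fit$iter < max_iter && !monotone
  if (!converged) {
    warning("possible monotone partial likelihood; fit flagged as non-converged")
  }
  structure(list(
    table = data.frame(term = colnames(x), coef = coef, se = se, z = z, p = p,
                       row.names = colnames(x)),
    loglik = fit$loglik[length(fit$loglik)],
    iterations = fit$iter, converged = converged,
    n_samples = nrow(x), n_events = sum(event),
    ties = ties
  ), class = "cox_fit")
}

#' Proportional-hazards check via scaled Schoenfeld residuals
#'
#' Tests, per covariate, for a nonzero slope of the scaled Schoenfeld
#' residuals against the event-time rank (the `cox.zph` score test with the
#' rank transform), plus a global test.
#'
#' @param time,event,covariates as in [fit_cox()].
#' @param ties tie correction.
#' @return `data.frame` with per-covariate `rho` (correlation of scaled
#'   residuals with event-time rank) and `p`, with the global p in attribute
#'   `global_p`.
#' @export
ph_check <- function(time, event, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (sum(event) < 3) stop("at least 3 events are required for the PH check")
  x <- as.matrix(covariates)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  df <- data.frame(time = time, event = event, x, check.names = FALSE)
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(sprintf("`%s`", colnames(x)), collapse = " + ")))
  fit <- survival::coxph(fml, data = df, ties = ties)
  zph <- survival::cox.zph(fit, transform = "rank")
  resid <- as.matrix(zph$y)
  rho <- apply(resid, 2, function(r) stats::cor(zph$x, r))
  tab <- as.data.frame(zph$table)
  per <- tab[rownames(tab) != "GLOBAL", , drop = FALSE]
  out <- data.frame(term = colnames(x), rho = rho, chisq = per$chisq,
                    p = per$p, row.names = colnames(x))
  attr(out, "global_p") <- tab["GLOBAL", "p"]
  out
}

#' Genomic inflation factor
#'
#' `lambda = median(qchisq(1 - p, 1)) / qchisq(0.5, 1)`: the ratio of the
#' median observed association chi-squared statistic to the null chi-squared
#' median (0.4549364). Values near 1 indicate adequate control of
#' confounding/batch structure; the EWAS diagnostics aim for the ~1.0-1.1
#' regime.
#'
#' @param pvals p-values in (0, 1\]; at least 10 required. Zeros are clipped
#'   to the smallest positive double with a warning.
#' @return The inflation factor (positive scalar).
#' @export
genomic_lambda <- function(pvals) {
  pvals <- pvals[!is.na(pvals)]
  stopifnot(length(pvals) >= 10, all(pvals <= 1), all(pvals >= 0))
  if (any(pvals == 0)) {
    warning("zero p-values clipped to the smallest positive double")
    pvals[pvals == 0] <- .Machine$double.xmin
  }
  chisq <- stats::qchisq(pvals, df = 1, lower.tail = FALSE)
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}

#' Benjamini-Hochberg q-values
#'
#' Standard step-up false-discovery-rate q-values; monotone nondecreasing in
#' p and always >= p elementwise.
#'
#' @param pvals p-values in \[0,1\] (NAs preserved).
#' @return q-values, same length and order as the input.
#' @export
bh_fdr <- function(pvals) {
  stats::p.adjust(pvals, method = "BH")
}
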
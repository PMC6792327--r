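# Shared fixtures, built once per test run.

fixture_env <- new.env(parent = emptyenv())

# Small annotation + two-module cohort used across unit tests.
small_scene <- function() {
  if (is.null(fixture_env$small)) {
    ann <- generate_annotation(1000, n_chroms = 2, clock_size = 50, seed = 101)
    spec <- default_module_spec(1000, sizes = c(80, 60), seed = 102,
                                hazard_coef = c(0.3, 0),
                                exposure_coef = c(0.5, 0))
    cohort <- generate_cohort(spec, ann, n_samples = 250, seed = 103)
    truth <- rep(0L, 1000)
    for (k in seq_along(spec$member_index)) truth[spec$member_index[[k]]] <- k
    names(truth) <- ann$cpg_id
    fixture_env$small <- list(ann = ann, spec = spec, cohort = cohort,
                              truth = truth,
                              modules = module_set_from_assignment(truth))
  }
  fixture_env$small
}

# Hand-built ACF table with constant correlation, for closed-form checks.
make_acf <- function(sigma, step = 50, n_bins = 2) {
  out <- data.frame(lo = (seq_len(n_bins) - 1L) * step + 1L,
                    hi = seq_len(n_bins) * step + 1L,
                    cor = sigma,
                    sigma = pmin(pmax(sigma, 0), 1 - 1e-8),
                    n_pairs = 100L)
  attr(out, "step") <- step
  attr(out, "max_dist") <- n_bins * step
  class(out) <- c("acf_table", "data.frame")
  out
}

# Explicit one-covariate Cox partial log-likelihood (Breslow or Efron ties),
# independent of the fitting engine; used as a grid-search oracle.
partial_loglik <- function(beta, time, event, x, ties = "efron") {
  ll <- 0
  for (tt in unique(time[event == 1])) {
    d_idx <- which(time == tt & event == 1)
    r_idx <- which(time >= tt)
    d <- length(d_idx)
    sum_d <- sum(exp(beta * x[d_idx]))
    sum_r <- sum(exp(beta * x[r_idx]))
    ll <- ll + sum(beta * x[d_idx])
    for (l in seq_len(d) - 1) {
      adj <- if (ties == "efron") (l / d) * sum_d else 0
      ll <- ll - log(sum_r - adj)
    }
  }
  ll
}

grid_cox_mle <- function(time, event, x, ties = "efron") {
  stats::optimize(function(b) partial_loglik(b, time, event, x, ties),
                  c(-25, 25), maximum = TRUE, tol = 1e-8)$maximum
}
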
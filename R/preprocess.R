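#' Sample-level detection quality control
#'
#' Removes samples with more than `max_undetected_frac` of probes undetected
#' at the detection threshold (`detection_p >= threshold_p`). The "more than"
#' rule is a strict inequality: a sample with exactly the threshold fraction
#' undetected is retained.
#'
#' @param detection_p samples x CpGs matrix of detection p-values, with sample
#'   ids as row names.
#' @param threshold_p detection threshold; a probe counts as undetected in a
#'   sample when its detection p-value is at or above this (default 1e-16).
#' @param max_undetected_frac maximum tolerated undetected fraction (0.10).
#' @return Character vector of retained sample ids, input order preserved.
#' @export
sample_qc <- function(detection_p, threshold_p = 1e-16,
                      max_undetected_frac = 0.10) {
  if (is.null(dim(detection_p)) || any(dim(detection_p) == 0)) {
    stop("empty detection p-value matrix")
  }
  frac <- rowMeans(detection_p >= threshold_p)
  ids <- rownames(detection_p) %||% as.character(seq_len(nrow(detection_p)))
  ids[frac <= max_undetected_frac]
}

#' Probe-level quality control
#'
#' Removes probes undetected in more than 10% of samples at the detection
#' threshold, probes on the X or Y chromosome, and probes in any supplied
#' exclusion list (cross-hybridizing, SNP-at-CpG, SNP-at-single-base-extension,
#' non-CpG probes — curated lists consumed as inputs). Boundary fractions are
#' retained (strict inequality).
#'
#' @param detection_p samples x CpGs detection p-value matrix with CpG ids as
#'   column names.
#' @param annotation annotation table with `cpg_id` and `chrom` columns.
#' @param exclusion_lists list of character vectors of CpG ids to drop; ids
#'   absent from the annotation are ignored with a warning.
#' @param threshold_p,max_undetected_frac as in [sample_qc()].
#' @return Character vector of retained CpG ids, annotation order preserved.
#' @export
probe_qc <- function(detection_p, annotation, exclusion_lists = list(),
                     threshold_p = 1e-16, max_undetected_frac = 0.10) {
  if (is.null(dim(detection_p)) || any(dim(detection_p) == 0)) {
    stop("empty detection p-value matrix")
  }
  cpgs <- annotation$cpg_id
  frac <- colMeans(detection_p[, cpgs, drop = FALSE] >= threshold_p)
  drop <- frac > max_undetected_frac
  sexchrom <- annotation$chrom %in% c("chrX", "chrY", "X", "Y")
  excl <- unique(unlist(exclusion_lists))
  unknown <- setdiff(excl, cpgs)
  if (length(unknown) > 0) {
    warning(length(unknown), " exclusion-list ids absent from annotation; ignored")
  }
  cpgs[!(drop | sexchrom | cpgs %in% excl)]
}

#' IQR-based outlier mask for one CpG
#'
#' Retains values inside `[Q1 - k*IQR, Q3 + k*IQR]`; quartiles use linear
#' interpolation (R quantile type 7). With zero IQR (all values identical)
#' nothing is masked. Missing values are reported as not retained.
#'
#' @param values numeric vector of one CpG's beta values across samples; at
#'   least 4 non-missing values are required.
#' @param k multiplier on the IQR (default 3).
#' @return Logical vector: TRUE for retained samples.
#' @export
iqr_outlier_mask <- function(values, k = 3) {
  ok <- !is.na(values)
  if (sum(ok) < 4) stop("need at least 4 non-missing values")
  q <- stats::quantile(values, c(0.25, 0.75), na.rm = TRUE, type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  ok & values >= q[1] - k * iqr & values <= q[2] + k * iqr
}

#' Principal components of control-probe intensities
#'
#' Computes technical covariates in the style of control-probe PCA: control
#' intensities are log2-transformed, standardized per probe across samples,
#' and decomposed by PCA. The top `k` score columns are returned, with each
#' component's sign fixed so that the largest-magnitude loading entry is
#' positive (making scores reproducible in sign).
#'
#' @param control_probes samples x probes matrix of positive intensities.
#' @param k number of components to return (default 7).
#' @return List of class `control_pcs`: `scores` (samples x k), `var_frac`
#'   (nonincreasing variance fractions), `rotation`.
#' @export
control_probe_pca <- function(control_probes, k = 7) {
  stopifnot(ncol(control_probes) >= k)
  if (any(control_probes <= 0)) stop("control intensities must be positive")
  x <- log2(control_probes)
  sds <- apply(x, 2, stats::sd)
  keep <- sds > 0
  if (!all(keep)) {
    warning(sum(!keep), " constant control probes dropped")
    x <- x[, keep, drop = FALSE]
    sds <- sds[keep]
  }
  xs <- scale(x)
  sv <- svd(xs)
  tol <- max(dim(xs)) * .Machine$double.eps * sv$d[1]
  r <- sum(sv$d > tol)
  if (k > r) {
    warning("requested ", k, " components but rank is ", r,
            "; returning ", r)
    k <- r
  }
  rotation <- sv$v[, seq_len(k), drop = FALSE]
  flip <- apply(rotation, 2, function(v) sign(v[which.max(abs(v))]))
  rotation <- sweep(rotation, 2, flip, `*`)
  scores <- xs %*% rotation
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(rotation) <- colnames(x)
  colnames(rotation) <- colnames(scores)
  var_frac <- (sv$d^2 / sum(sv$d^2))[seq_len(k)]
  structure(list(scores = scores, var_frac = var_frac, rotation = rotation),
            class = "control_pcs")
}

#' Reference-based blood cell-fraction estimation
#'
#' Houseman-style deconvolution: per sample, solve the constrained least
#' squares problem `min || beta_s - reference %*% f ||^2` subject to
#' `f >= 0, sum(f) <= 1` (the sum constraint is imposed through a penalized
#' nonnegative slack variable), then renormalize the solution to sum exactly
#' to 1.
#'
#' @param beta samples x CpGs beta matrix with CpG ids as column names.
#' @param reference CpGs x cell-types signature matrix (row names = CpG ids);
#'   only CpGs present in `beta` are used.
#' @param penalty weight on the sum-constraint penalty row.
#' @return List of class `cell_fractions`: `fractions` (samples x cell types,
#'   rows summing to 1) and `residual` (per-sample residual norm).
#' @export
estimate_cell_fractions <- function(beta, reference, penalty = 1000) {
  common <- intersect(rownames(reference), colnames(beta))
  if (length(common) < ncol(reference)) {
    stop("too few signature CpGs shared with the beta matrix")
  }
  R <- reference[common, , drop = FALSE]
  if (qr(R)$rank < ncol(R)) stop("reference signature matrix is rank-deficient")
  p <- ncol(R)
  A <- rbind(cbind(R, 0), c(rep(penalty, p), penalty))
  n <- nrow(beta)
  fractions <- matrix(NA_real_, n, p,
                      dimnames = list(rownames(beta), colnames(R)))
  residual <- numeric(n)
  for (s in seq_len(n)) {
    b <- c(beta[s, common], penalty)
    sol <- pracma::lsqnonneg(A, b)
    f <- sol$x[seq_len(p)]
    if (sum(f) <= 0) {
      warning("all-zero solution for sample ", s, "; uniform fractions used")
      f <- rep(1 / p, p)
    }
    residual[s] <- sqrt(sum((beta[s, common] - as.vector(R %*% f))^2))
    fractions[s, ] <- f / sum(f)
  }
  structure(list(fractions = fractions, residual = residual),
            class = "cell_fractions")
}

#' Prepare phenotype covariates for modeling
#'
#' Applies the covariate conventions used throughout the survival models:
#' blood biomarkers (total cholesterol, LDL, HDL, triglycerides, glucose,
#' hsCRP, systolic blood pressure) are log10-transformed; missing BMI,
#' medication flags and smoking status are median-imputed (so missing smoking
#' or medication becomes 0 when the observed median is 0); a diabetes flag is
#' derived as diabetes medication use OR fasting glucose above 125 mg/dL (on
#' the original scale, before the log transform); and pack-years, where not
#' directly observed, is approximated as years since starting smoking times
#' current packs per day. Missing survival fields or biomarkers are errors:
#' imputation never applies to them.
#'
#' @param phenotypes phenotype `data.frame` (see [generate_cohort()] for the
#'   column layout).
#' @param biomarkers names of the columns to log10-transform.
#' @param impute names of the columns to median-impute.
#' @return The transformed phenotype `data.frame`, with a `diabetes` column
#'   added.
#' @export
prepare_covariates <- function(phenotypes,
                               biomarkers = c("chol", "ldl", "hdl", "tg",
                                              "glu", "hscrp", "sbp"),
                               impute = c("bmi", "smoking_status", "bp_med",
                                          "lipid_med", "diabetes_med")) {
  ph <- phenotypes
  for (col in c("time", "event")) {
    if (any(is.na(ph[[col]]))) stop("missing values in survival field '", col, "'")
  }
  biomarkers <- intersect(biomarkers, names(ph))
  for (col in biomarkers) {
    v <- ph[[col]]
    if (any(is.na(v))) stop("missing biomarker '", col, "' (imputation does not apply)")
    bad <- which(v <= 0)
    if (length(bad) > 0) {
      stop("nonpositive value in biomarker '", col, "' for sample ",
           (ph$sample_id %||% rownames(ph))[bad[1]])
    }
  }
  glu_raw <- if ("glu" %in% names(ph)) ph$glu else NULL
  for (col in biomarkers) ph[[col]] <- log10(ph[[col]])
  for (col in intersect(impute, names(ph))) {
    v <- ph[[col]]
    if (any(is.na(v))) ph[[col]][is.na(v)] <- stats::median(v, na.rm = TRUE)
  }
  if (!is.null(glu_raw) && "diabetes_med" %in% names(ph)) {
    ph$diabetes <- as.integer(ph$diabetes_med == 1 | glu_raw > 125)
  }
  if ("pack_years" %in% names(ph) && any(is.na(ph$pack_years)) &&
      all(c("years_smoking", "packs_per_day") %in% names(ph))) {
    miss <- is.na(ph$pack_years)
    ph$pack_years[miss] <- ph$years_smoking[miss] * ph$packs_per_day[miss]
  }
  ph
}
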
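#' Remove features with excessive missingness
#'
#' Applies, in order: (i) drop features with zero intensity in more than
#' `max_test_missing` of study samples; (ii) drop features with zero
#' intensity in more than `max_qc_missing` of QC injections; (iii) keep
#' only features detected (non-zero) in more than `min_test_presence` of
#' study samples. With the defaults a feature must be missing in no more
#' than 80% of study samples and 50% of QCs, and present in over half
#' the study samples.
#'
#' @param m a [metabo_matrix()].
#' @param max_test_missing maximum tolerated missing fraction in study
#'   samples.
#' @param max_qc_missing maximum tolerated missing fraction in QC
#'   injections.
#' @param min_test_presence minimum detection fraction in study samples
#'   (strict inequality).
#' @return the filtered `metabo_matrix`.
#' @export
missingness_filter <- function(m, max_test_missing = 0.80,
                               max_qc_missing = 0.50,
                               min_test_presence = 0.50) {
  stopifnot(inherits(m, "metabo_matrix"))
  test <- study_intensity(m)
  if (nrow(test) == 0) stop("no study (non-QC) samples present")
  miss_test <- colMeans(test == 0)
  keep <- miss_test <= max_test_missing
  if (any(m$is_qc)) {
    miss_qc <- colMeans(qc_intensity(m) == 0)
    keep <- keep & miss_qc <= max_qc_missing
  } else {
    warning("no QC samples: skipping the QC missingness rule")
  }
  keep <- keep & colMeans(test > 0) > min_test_presence
  subset_features(m, keep)
}

# Fit the QC drift curve for one feature: penalized spline of log
# intensity on injection order through the non-zero QC points. Returns
# the fitted intensity-scale curve evaluated at `orders`, or NULL when a
# trend cannot (or should not) be fit, in which case the caller falls
# back to the constant median curve.
fit_qc_curve <- function(qc_order, qc_value, orders, min_qc = 5) {
  ok <- qc_value > 0
  if (sum(ok) < min_qc) return(NULL)
  df <- data.frame(o = qc_order[ok], y = log(qc_value[ok]))
  kk <- max(3, min(6, nrow(df) - 1))
  fit <- tryCatch(
    mgcv::gam(y ~ s(o, k = kk), data = df),
    error = function(e) NULL
  )
  if (is.null(fit)) return(NULL)
  exp(as.numeric(stats::predict(fit, newdata = data.frame(o = orders))))
}

#' Correct injection-order drift against pooled QC injections
#'
#' Per feature, a smooth curve f(order) is fit to the non-zero QC
#' intensities (penalized spline on the log scale) and every intensity is
#' divided by f(order)/median(QC), anchoring the feature at its QC
#' median. Zeros (missing values) are left untouched. The correction for
#' a feature is only accepted when it does not increase that feature's
#' QC relative standard deviation; otherwise, and whenever fewer than
#' `min_qc` usable QC points exist, the fitted curve degenerates to the
#' constant QC median, which leaves the data unchanged.
#'
#' @param m a [metabo_matrix()] with QC injections flagged.
#' @param min_qc minimum number of non-zero QC points needed to fit a
#'   trend (below this a warning is emitted and the constant median
#'   curve is used).
#' @return the drift-corrected `metabo_matrix`.
#' @export
drift_correct <- function(m, min_qc = 5) {
  stopifnot(inherits(m, "metabo_matrix"))
  if (sum(m$is_qc) < 2) stop("drift correction needs at least 2 QC samples")
  if (sum(m$is_qc) < min_qc) {
    warning("fewer than ", min_qc,
            " QC injections: using constant median scaling (no drift fit)")
  }
  qc_idx <- which(m$is_qc)
  orders <- m$injection_order
  out <- m$intensity
  for (j in seq_len(ncol(out))) {
    x <- out[, j]
    qc <- x[qc_idx]
    med <- stats::median(qc[qc > 0])
    if (!is.finite(med) || med <= 0) next
    f <- fit_qc_curve(orders[qc_idx], qc, orders, min_qc = min_qc)
    if (is.null(f)) next  # constant curve f == med: x * med/med = x
    corrected <- ifelse(x > 0, x * med / f, 0)
    if (feature_rsd(corrected[qc_idx]) <= feature_rsd(qc) + 1e-12) {
      out[, j] <- corrected
    }
  }
  m$intensity <- out
  m
}

# RSD (sd/mean) over the non-zero entries of a QC intensity vector.
feature_rsd <- function(qc_values) {
  v <- qc_values[qc_values > 0]
  if (length(v) < 2) return(NA_real_)
  stats::sd(v) / mean(v)
}

#' Remove features with unstable QC measurements
#'
#' Drops features whose relative standard deviation (sd/mean over the
#' non-zero QC intensities) is strictly above `max_rsd`; a feature with
#' fewer than two non-zero QC values cannot be assessed and is removed.
#'
#' @param m a [metabo_matrix()] with >= 2 QC injections.
#' @param max_rsd maximum tolerated QC RSD (default 0.30, i.e. 30%).
#' @return the filtered `metabo_matrix`; the removed feature ids are
#'   attached as attribute `"removed"`.
#' @export
rsd_filter <- function(m, max_rsd = 0.30) {
  stopifnot(inherits(m, "metabo_matrix"))
  if (sum(m$is_qc) < 2) stop("RSD filter needs at least 2 QC samples")
  rsd <- apply(qc_intensity(m), 2, feature_rsd)
  keep <- !is.na(rsd) & rsd <= max_rsd
  removed <- colnames(m$intensity)[!keep]
  m <- subset_features(m, keep)
  attr(m, "removed") <- removed
  m
}

#' Keep features at given MSI annotation confidence levels
#'
#' @param m a [metabo_matrix()] with an annotation table.
#' @param msi_levels annotation levels to retain (default 1 and 2, the
#'   identified / putatively annotated tiers).
#' @return `metabo_matrix` restricted to those features.
#' @export
select_annotated <- function(m, msi_levels = c(1, 2)) {
  stopifnot(inherits(m, "metabo_matrix"))
  if (is.null(m$annotation)) stop("no annotation table attached")
  keep <- m$annotation$msi_level %in% msi_levels
  subset_features(m, keep)
}

#' Transform one metabolite feature for association modelling
#'
#' Missing values (zeros) are imputed at the observed minimum (or half
#' the minimum), the vector is log10-transformed, and then z-standardized
#' using the mean and population (1/n) standard deviation of the
#' originally observed (non-missing) entries.
#'
#' @param values non-negative intensity vector; 0 encodes missing.
#' @param impute `"min"` (default) or `"halfmin"`.
#' @return standardized numeric vector with attribute `"imputed"` giving
#'   the indices that were imputed.
#' @export
transform_metabolite <- function(values, impute = c("min", "halfmin")) {
  impute <- match.arg(impute)
  if (all(values == 0)) stop("all values missing: cannot transform")
  if (any(values < 0)) stop("negative intensities")
  missing_idx <- which(values == 0)
  fill <- min(values[values > 0])
  if (impute == "halfmin") fill <- fill / 2
  values[missing_idx] <- fill
  lg <- log10(values)
  obs <- if (length(missing_idx)) lg[-missing_idx] else lg
  s <- sqrt(mean((obs - mean(obs))^2))
  z <- if (is.na(s) || s == 0) rep(0, length(lg)) else (lg - mean(obs)) / s
  attr(z, "imputed") <- missing_idx
  z
}

# Transform every feature of the study (non-QC) intensity matrix; returns
# a samples x features matrix of standardized log10 intensities.
transform_study_matrix <- function(m, impute = "min") {
  x <- study_intensity(m)
  out <- vapply(seq_len(ncol(x)), function(j) {
    as.numeric(transform_metabolite(x[, j], impute = impute))
  }, numeric(nrow(x)))
  dimnames(out) <- dimnames(x)
  out
}
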
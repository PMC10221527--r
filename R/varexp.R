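# Minimum-norm least-squares coefficients via the SVD pseudo-inverse;
# collinear predictor matrices (common when presence and abundance
# encodings overlap) stay well-defined.
min_norm_lsfit <- function(X, y, tol = 1e-10) {
  s <- svd(X)
  pos <- s$d > tol * s$d[1]
  if (!any(pos)) return(rep(0, ncol(X)))
  s$v[, pos, drop = FALSE] %*%
    ((crossprod(s$u[, pos, drop = FALSE], y)) / s$d[pos])
}

# One-metabolite two-part p-values against every taxon (train subset);
# same model as run_association_scan but for a single response.
two_part_pvalues <- function(y_resid, prop, quant_only_prev = 0.95,
                             min_present = 10, min_per_class = 3) {
  n <- length(y_resid)
  vapply(seq_len(ncol(prop)), function(j) {
    pres <- prop[, j] > 0
    npres <- sum(pres)
    zb <- NA_real_
    if (mean(pres) < quant_only_prev && npres >= min_per_class &&
        n - npres >= min_per_class && stats::sd(y_resid) > 0) {
      b <- binary_part(y_resid, pres, min_per_class)
      if (!is.null(b)) zb <- b$z
    }
    zq <- NA_real_
    if (npres >= min_present) {
      q <- quant_part(y_resid, prop[, j], pres, min_present)
      if (!is.null(q)) zq <- q$z
    }
    if (is.na(zb) && is.na(zq)) return(NA_real_)
    meta_unweighted_z(if (is.na(zb)) NA else zb,
                      if (is.na(zq)) NA else zq)$p_value
  }, numeric(1))
}

# Presence + zero-filled standardized log-abundance design matrix for
# the selected taxa, using train-derived standardization parameters.
varexp_design <- function(prop, selected, center, scale_) {
  blocks <- lapply(seq_along(selected), function(k) {
    j <- selected[k]
    pres <- as.numeric(prop[, j] > 0)
    z <- rep(0, nrow(prop))
    idx <- which(pres == 1)
    if (length(idx) && is.finite(scale_[k]) && scale_[k] > 0) {
      z[idx] <- (log10(prop[idx, j]) - center[k]) / scale_[k]
    }
    cbind(pres, z)
  })
  do.call(cbind, blocks)
}

#' Cross-validated variance of a metabolite explained by the microbiota
#'
#' Estimates, by repeated random train/test splits, the proportion of a
#' serum metabolite's variance that one gut location's microbiota can
#' predict. Per round: the cohort is split (default 90/10); taxa
#' associated with the metabolite on the training set (two-part p <
#' `selection_alpha`) are selected; a linear predictor of presence
#' indicators plus zero-filled standardized log abundances of the
#' selected taxa is fit by minimum-norm least squares on the
#' covariate-residualized metabolite; and the out-of-sample R-squared
#' `1 - SSE/SST` is computed on the held-out samples (SST around the
#' training mean). A round selecting no taxon contributes R-squared 0.
#' The estimate is the median over rounds, clamped to \[0, 1\]. An
#' optional permutation p-value rebuilds the whole procedure (at
#' `perm_rounds` rounds) on label-permuted data.
#'
#' @param metabolite raw intensity vector named by sample id, or a
#'   single feature id present in `metabolites`.
#' @param taxa a [taxa_table()].
#' @param metabolites optional [metabo_matrix()] (required when
#'   `metabolite` is a feature id).
#' @param covariates optional covariate data.frame (rownames = sample
#'   ids).
#' @param n_rounds number of cross-validation rounds.
#' @param test_frac held-out fraction per round.
#' @param selection_alpha two-part p-value threshold for taxon selection
#'   on the training set.
#' @param n_perm permutations for the p-value (0 = skip, p = NA).
#' @param perm_rounds rounds per permutation.
#' @param seed integer seed.
#' @return list of class `varexp_estimate`: `metabolite_id`, `location`,
#'   `r2_cv`, `r2_rounds`, `n_rounds`, `selected_per_round`, `p_value`.
#' @export
variance_explained <- function(metabolite, taxa, metabolites = NULL,
                               covariates = NULL, n_rounds = 100,
                               test_frac = 0.1, selection_alpha = 0.05,
                               n_perm = 0, perm_rounds = 20, seed = 1L) {
  stopifnot(inherits(taxa, "taxa_table"))
  metabolite_id <- "metabolite"
  if (is.character(metabolite) && length(metabolite) == 1) {
    stopifnot(inherits(metabolites, "metabo_matrix"))
    metabolite_id <- metabolite
    y_raw <- study_intensity(metabolites)[, metabolite]
  } else {
    y_raw <- metabolite
    if (!is.null(names(metabolite))) metabolite_id <- "metabolite"
  }
  ids <- sort(intersect(rownames(taxa$abundance), names(y_raw)))
  if (length(ids) < 50) stop("need at least 50 overlapping samples")
  ab <- taxa$abundance[ids, , drop = FALSE]
  prop <- sweep(ab, 1, rowSums(ab), "/")
  cov_df <- align_covariates(covariates, ids)
  y <- residualize(as.numeric(transform_metabolite(y_raw[ids])), cov_df)

  set.seed(seed)
  run_rounds <- function(yy, rounds) {
    n <- length(yy)
    n_test <- max(1L, round(test_frac * n))
    r2 <- numeric(rounds)
    nsel <- integer(rounds)
    for (r in seq_len(rounds)) {
      test <- sample.int(n, n_test)
      train <- setdiff(seq_len(n), test)
      pv <- two_part_pvalues(yy[train] - mean(yy[train]),
                             prop[train, , drop = FALSE])
      sel <- which(!is.na(pv) & pv < selection_alpha)
      nsel[r] <- length(sel)
      if (length(sel) == 0) { r2[r] <- 0; next }
      center <- scale_ <- numeric(length(sel))
      for (k in seq_along(sel)) {
        a <- prop[train, sel[k]]
        la <- log10(a[a > 0])
        center[k] <- mean(la)
        scale_[k] <- stats::sd(la)
      }
      Xtr <- varexp_design(prop[train, , drop = FALSE], sel, center, scale_)
      Xte <- varexp_design(prop[test, , drop = FALSE], sel, center, scale_)
      mu <- mean(yy[train])
      beta <- min_norm_lsfit(cbind(1, Xtr), yy[train])
      pred <- as.numeric(cbind(1, Xte) %*% beta)
      sse <- sum((yy[test] - pred)^2)
      sst <- sum((yy[test] - mu)^2)
      r2[r] <- if (sst > 0) 1 - sse / sst else 0
    }
    list(r2 = r2, nsel = nsel)
  }

  obs <- run_rounds(y, n_rounds)
  est <- min(max(stats::median(obs$r2), 0), 1)

  p_value <- NA_real_
  if (n_perm > 0) {
    perm_stats <- vapply(seq_len(n_perm), function(i) {
      yp <- sample(y)
      min(max(stats::median(run_rounds(yp, perm_rounds)$r2), 0), 1)
    }, numeric(1))
    p_value <- (1 + sum(perm_stats >= est)) / (1 + n_perm)
  }

  structure(list(metabolite_id = metabolite_id,
                 location = taxa$location,
                 r2_cv = est,
                 r2_rounds = obs$r2,
                 n_rounds = n_rounds,
                 selected_per_round = obs$nsel,
                 p_value = p_value),
            class = "varexp_estimate")
}

#' @export
print.varexp_estimate <- function(x, ...) {
  cat(sprintf(
    "variance explained: %s (%s) r2_cv = %.4f over %d rounds (p = %s)\n",
    x$metabolite_id, x$location, x$r2_cv, x$n_rounds,
    ifelse(is.na(x$p_value), "not computed", format(x$p_value))))
  invisible(x)
}
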
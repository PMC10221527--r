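#' Residualize a response on nuisance covariates
#'
#' Ordinary least-squares residuals of `y` on an intercept plus the given
#' covariates (e.g. sex and slaughter batch as factors). Aliased columns
#' in a rank-deficient design are dropped with a message.
#'
#' @param y numeric response vector.
#' @param covariates data.frame of covariates aligned with `y`, or NULL
#'   (then `y` is simply centred).
#' @return residual vector (mean zero).
#' @export
residualize <- function(y, covariates = NULL) {
  if (is.null(covariates) || ncol(as.data.frame(covariates)) == 0) {
    return(y - mean(y))
  }
  X <- stats::model.matrix(~ ., data = as.data.frame(covariates))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    message("residualize: dropping aliased column(s): ",
            paste(dropped, collapse = ", "))
  }
  as.numeric(qr.resid(qrX, y))
}

# t statistic of the OLS slope of y on x, via the Pearson correlation.
# Reported as a Z score (no df correction; at the cohort sizes this
# pipeline targets, t and z are interchangeable).
t_from_cor <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  ifelse(abs(r) >= 1, sign(r) * Inf, r * sqrt((n - 2) / (1 - r^2)))
}

#' Binary (presence/absence) part of the two-part model
#'
#' Tests whether a taxon's detection status shifts the metabolite level:
#' the slope z-statistic of the covariate-residualized metabolite on the
#' 0/1 presence indicator (equivalent to a two-sample comparison of
#' means).
#'
#' @param y_resid covariate-residualized metabolite values.
#' @param presence 0/1 detection indicator.
#' @param min_per_class minimum samples required in each class.
#' @return list with `z`, `beta` (mean shift when present), `n`; or
#'   `NULL` when the part cannot run (a class too small, or a constant
#'   response).
#' @export
binary_part <- function(y_resid, presence, min_per_class = 3) {
  presence <- as.numeric(presence > 0)
  n <- length(y_resid)
  n1 <- sum(presence)
  if (n1 < min_per_class || n - n1 < min_per_class) return(NULL)
  if (stats::sd(y_resid) == 0) return(NULL)
  r <- stats::cor(presence, y_resid)
  beta <- mean(y_resid[presence == 1]) - mean(y_resid[presence == 0])
  list(z = t_from_cor(r, n), beta = beta, n = n)
}

#' Quantitative (abundance given presence) part of the two-part model
#'
#' Among samples where the taxon is detected, tests the slope of the
#' covariate-residualized metabolite on the z-standardized log10
#' relative abundance.
#'
#' @param y_resid covariate-residualized metabolite values.
#' @param abundance relative abundances (same length as `y_resid`).
#' @param presence optional 0/1 detection indicator; defaults to
#'   `abundance > 0`.
#' @param min_present minimum number of detected samples.
#' @return list with `z`, `beta` (slope per sd of log abundance), `n`
#'   (detected samples used); or `NULL` when the part cannot run.
#' @export
quant_part <- function(y_resid, abundance, presence = NULL,
                       min_present = 10) {
  if (is.null(presence)) presence <- abundance > 0
  idx <- which(presence > 0)
  if (length(idx) < min_present) return(NULL)
  a <- log10(abundance[idx])
  if (stats::sd(a) == 0 || stats::sd(y_resid[idx]) == 0) return(NULL)
  x <- as.numeric(scale(a))
  r <- stats::cor(x, y_resid[idx])
  beta <- r * stats::sd(y_resid[idx])
  list(z = t_from_cor(r, length(idx)), beta = beta, n = length(idx))
}

#' Combine the two sub-model Z scores by unweighted (Stouffer) meta-analysis
#'
#' `z_meta = (z_binary + z_quant) / sqrt(2)`; when only one part ran, the
#' combined score is that part's Z. The p-value is the two-sided normal
#' tail probability.
#'
#' @param z_binary Z score of the binary part, or NA if it did not run.
#' @param z_quant Z score of the quantitative part, or NA if it did not
#'   run.
#' @return list with `z_meta` and `p_value`.
#' @export
meta_unweighted_z <- function(z_binary, z_quant) {
  zs <- c(z_binary, z_quant)
  zs <- zs[is.finite(zs) | (!is.na(zs) & is.infinite(zs))]
  if (length(zs) == 0) stop("no sub-model Z score available")
  z <- if (length(zs) == 2) sum(zs) / sqrt(2) else zs
  list(z_meta = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param p vector of p-values in (0, 1].
#' @return q-values (BH-adjusted p-values).
#' @export
bh_adjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Two-part association scan of all taxon x metabolite pairs
#'
#' Runs the two-part model for every (taxon, metabolite) pair of one gut
#' location at one taxonomic level: metabolites are log10-transformed,
#' standardized and residualized on the covariates; each taxon is split
#' into a presence/absence indicator and a log-abundance-given-presence
#' predictor; sub-model Z scores are combined by unweighted Z
#' meta-analysis and BH-adjusted within the scan (one location x level
#' family).
#'
#' Which parts run is set by a prevalence policy: taxa detected in at
#' least `quant_only_prev` of samples contribute only the quantitative
#' part (presence nearly constant); taxa with fewer than `min_present`
#' detected samples contribute only the binary part; otherwise both
#' parts run.
#'
#' @param taxa a [taxa_table()] (counts or proportions; proportions are
#'   computed internally).
#' @param metabolites a [metabo_matrix()]; only study (non-QC) samples
#'   are used, matched to the taxa table by sample id.
#' @param covariates optional data.frame of per-sample covariates with
#'   rownames as sample ids (e.g. sex, batch).
#' @param min_overlap minimum number of overlapping samples.
#' @param quant_only_prev prevalence at or above which only the
#'   quantitative part runs.
#' @param min_present minimum detected samples for the quantitative part.
#' @param min_per_class minimum class size for the binary part.
#' @param impute missing-value imputation passed to
#'   [transform_metabolite()].
#' @return data.frame of class `association_scan`, one row per testable
#'   pair, sorted by p-value, with columns `taxon_id`, `metabolite_id`,
#'   `location`, `level`, `prevalence`, `z_binary`, `z_quant`, `z_meta`,
#'   `p_value`, `q_value`, `parts_run`, `direction`, `n_used`.
#' @export
run_association_scan <- function(taxa, metabolites, covariates = NULL,
                                 min_overlap = 30,
                                 quant_only_prev = 0.95,
                                 min_present = 10,
                                 min_per_class = 3,
                                 impute = "min") {
  stopifnot(inherits(taxa, "taxa_table"), inherits(metabolites, "metabo_matrix"))
  Yraw <- study_intensity(metabolites)
  ids <- intersect(rownames(taxa$abundance), rownames(Yraw))
  if (length(ids) < min_overlap) {
    stop("only ", length(ids), " overlapping samples (need >= ",
         min_overlap, ")")
  }
  ids <- sort(ids)  # invariant to input sample order
  ab <- taxa$abundance[ids, , drop = FALSE]
  prop <- sweep(ab, 1, rowSums(ab), "/")
  Yraw <- Yraw[ids, , drop = FALSE]
  cov_df <- align_covariates(covariates, ids)

  n <- length(ids)
  Yres <- apply(Yraw, 2, function(v) {
    residualize(transform_metabolite(v, impute = impute), cov_df)
  })
  y_ok <- apply(Yres, 2, stats::sd) > 0

  res <- vector("list", ncol(prop))
  for (j in seq_len(ncol(prop))) {
    pres <- prop[, j] > 0
    prev <- mean(pres)
    npres <- sum(pres)
    want_binary <- prev < quant_only_prev &&
      npres >= min_per_class && (n - npres) >= min_per_class
    want_quant <- npres >= min_present
    if (!want_binary && !want_quant) next

    zb <- rep(NA_real_, ncol(Yres))
    if (want_binary) {
      r <- suppressWarnings(stats::cor(as.numeric(pres), Yres))
      zb <- ifelse(y_ok, t_from_cor(as.numeric(r), n), NA_real_)
    }
    zq <- rep(NA_real_, ncol(Yres))
    nq <- npres
    if (want_quant) {
      a <- log10(prop[pres, j])
      if (stats::sd(a) > 0) {
        x <- as.numeric(scale(a))
        Ysub <- Yres[pres, , drop = FALSE]
        sub_ok <- apply(Ysub, 2, stats::sd) > 0
        r <- suppressWarnings(stats::cor(x, Ysub))
        zq <- ifelse(sub_ok, t_from_cor(as.numeric(r), npres), NA_real_)
      }
    }
    both <- !is.na(zb) & !is.na(zq)
    one <- xor(is.na(zb), is.na(zq))
    keep <- both | one
    if (!any(keep)) next
    z_meta <- ifelse(both, (zb + zq) / sqrt(2),
                     ifelse(is.na(zb), zq, zb))
    parts <- ifelse(both, "both", ifelse(is.na(zb), "quant_only",
                                         "binary_only"))
    n_used <- ifelse(parts == "quant_only", nq, n)
    res[[j]] <- data.frame(
      taxon_id = colnames(prop)[j],
      metabolite_id = colnames(Yres),
      location = taxa$location,
      level = taxa$level,
      prevalence = prev,
      z_binary = zb,
      z_quant = zq,
      z_meta = z_meta,
      parts_run = parts,
      n_used = n_used,
      row.names = NULL
    )[keep, , drop = FALSE]
  }
  out <- do.call(rbind, res)
  if (is.null(out) || nrow(out) == 0) {
    stop("no testable taxon x metabolite pair")
  }
  out$p_value <- 2 * stats::pnorm(-abs(out$z_meta))
  out$q_value <- bh_adjust(out$p_value)
  out$direction <- ifelse(out$z_meta >= 0, "+", "-")
  out <- out[order(out$p_value, out$taxon_id, out$metabolite_id), ]
  rownames(out) <- NULL
  class(out) <- c("association_scan", "data.frame")
  out
}

# Align a covariate data.frame (rownames or sample_id column) to ids.
align_covariates <- function(covariates, ids) {
  if (is.null(covariates)) return(NULL)
  covariates <- as.data.frame(covariates)
  if ("sample_id" %in% names(covariates)) {
    rownames(covariates) <- covariates$sample_id
    covariates$sample_id <- NULL
  }
  if (!all(ids %in% rownames(covariates))) {
    stop("covariates missing for some samples")
  }
  covariates[ids, , drop = FALSE]
}

#' Covariate-adjusted Spearman rank correlation
#'
#' Both variables are rank-transformed (average ranks on ties), the
#' ranks are residualized on the covariates, and the Pearson correlation
#' of the residuals is reported with a t-approximation p-value
#' (df = n - 2 - number of covariate columns).
#'
#' @param y,x numeric vectors of equal length (>= 10 pairs).
#' @param covariates optional covariate data.frame aligned with `y`.
#' @return list with `rho` and `p_value`.
#' @export
spearman_partial <- function(y, x, covariates = NULL) {
  n <- length(y)
  if (length(x) != n) stop("x and y lengths differ")
  if (n < 10) stop("need at least 10 paired observations")
  if (stats::sd(y) == 0 || stats::sd(x) == 0) {
    stop("constant vector: Spearman correlation undefined")
  }
  ry <- residualize(rank(y), covariates)
  rx <- residualize(rank(x), covariates)
  rho <- stats::cor(ry, rx)
  k <- n_covariate_cols(covariates)
  df <- n - 2 - k
  tt <- t_from_cor(rho, n - k)
  p <- 2 * stats::pt(-abs(tt), df = df)
  list(rho = rho, p_value = p)
}

n_covariate_cols <- function(covariates) {
  if (is.null(covariates)) return(0L)
  X <- stats::model.matrix(~ ., data = as.data.frame(covariates))
  qr(X)$rank - 1L
}

#' Validate two-part associations with covariate-adjusted Spearman
#'
#' Recomputes a covariate-adjusted Spearman correlation for every pair
#' the scan tested, BH-adjusts those p-values within the same family,
#' and reports which two-part-significant pairs are replicated
#' (Spearman q below the threshold with the same sign).
#'
#' @param scan an `association_scan` from [run_association_scan()].
#' @param taxa,metabolites,covariates the same inputs the scan used.
#' @param q_threshold significance level for both methods.
#' @return list with `table` (per significant pair: rho, spearman q,
#'   replicated flag), `n_significant`, `n_replicated`,
#'   `replication_fraction`.
#' @export
validate_with_spearman <- function(scan, taxa, metabolites,
                                   covariates = NULL, q_threshold = 0.05) {
  stopifnot(inherits(scan, "association_scan"))
  Yraw <- study_intensity(metabolites)
  ids <- sort(intersect(rownames(taxa$abundance), rownames(Yraw)))
  ab <- taxa$abundance[ids, , drop = FALSE]
  prop <- sweep(ab, 1, rowSums(ab), "/")
  Yraw <- Yraw[ids, , drop = FALSE]
  cov_df <- align_covariates(covariates, ids)
  n <- length(ids)
  k <- n_covariate_cols(cov_df)

  # standardized covariate-residualized ranks -> partial Spearman by
  # cross-product
  std_rank_resid <- function(v) {
    r <- residualize(rank(v), cov_df)
    s <- stats::sd(r)
    if (s == 0) rep(NA_real_, length(r)) else r / s
  }
  Ry <- apply(Yraw, 2, std_rank_resid)
  Rx <- apply(prop, 2, std_rank_resid)
  rho_all <- crossprod(Rx, Ry) / (n - 1)  # taxa x metabolites

  idx <- cbind(match(scan$taxon_id, colnames(prop)),
               match(scan$metabolite_id, colnames(Yraw)))
  rho <- rho_all[idx]
  tt <- t_from_cor(rho, n - k)
  sp_p <- 2 * stats::pt(-abs(tt), df = n - 2 - k)
  sp_q <- bh_adjust(sp_p)

  sig <- scan$q_value < q_threshold
  replicated <- sig & sp_q < q_threshold & sign(rho) == sign(scan$z_meta)
  tab <- data.frame(
    taxon_id = scan$taxon_id[sig],
    metabolite_id = scan$metabolite_id[sig],
    z_meta = scan$z_meta[sig],
    rho = rho[sig],
    spearman_q = sp_q[sig],
    replicated = replicated[sig],
    row.names = NULL
  )
  list(table = tab,
       n_significant = sum(sig),
       n_replicated = sum(replicated),
       replication_fraction = if (sum(sig) == 0) NA_real_
                              else sum(replicated) / sum(sig))
}
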
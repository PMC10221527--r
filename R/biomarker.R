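#' PLS-DA variable importance in projection (VIP) scores
#'
#' Fits a PLS1 model (NIPALS) of the centred binary group indicator on
#' the column-standardized feature matrix and returns per-feature VIP
#' scores:
#' `VIP_j = sqrt( p * sum_a SS_a (w_ja / ||w_a||)^2 / sum_a SS_a )`,
#' where `SS_a` is the response variance captured by component `a`.
#' By construction the VIP scores satisfy `sum_j VIP_j^2 = p`, so their
#' mean square is exactly 1 and VIP > 1 marks above-average importance.
#'
#' @param X samples x features matrix (standardized internally).
#' @param y binary group (factor with 2 levels, or 0/1), each class with
#'   >= 3 samples.
#' @param n_components number of PLS components (reduced with a warning
#'   when the data cannot support that many).
#' @return named numeric vector of VIP scores.
#' @export
plsda_vip <- function(X, y, n_components = 2) {
  X <- as.matrix(X)
  y01 <- binarize_labels(y)
  if (min(table(y01)) < 3) stop("each group needs at least 3 samples")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) stop("constant feature column(s): cannot standardize")
  E <- scale(X)
  f <- y01 - mean(y01)
  p <- ncol(E)
  W <- matrix(0, p, n_components)
  ss <- numeric(n_components)
  used <- 0
  for (a in seq_len(n_components)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t_sc <- E %*% w
    tt <- sum(t_sc^2)
    if (tt < 1e-12) break
    p_load <- crossprod(E, t_sc) / tt
    q <- sum(f * t_sc) / tt
    E <- E - t_sc %*% t(p_load)
    f <- f - t_sc * q
    W[, a] <- w
    ss[a] <- q^2 * tt
    used <- a
  }
  if (used < n_components) {
    warning("reduced to ", used, " PLS component(s)")
  }
  if (used == 0) stop("response carries no projectable variance")
  W <- W[, seq_len(used), drop = FALSE]
  ss <- ss[seq_len(used)]
  vip <- sqrt(p * as.numeric(W^2 %*% ss) / sum(ss))
  names(vip) <- colnames(X)
  vip
}

# Coerce a two-class label vector to 0/1 (second level / TRUE / max = 1).
binarize_labels <- function(y) {
  if (is.factor(y) || is.character(y)) {
    y <- as.factor(y)
    if (nlevels(droplevels(y)) != 2) stop("need exactly 2 groups")
    as.numeric(y == levels(y)[2])
  } else {
    u <- sort(unique(y))
    if (length(u) != 2) stop("need exactly 2 groups")
    as.numeric(y == u[2])
  }
}

#' Differential metabolites between two groups
#'
#' Per metabolite: a two-sided rank-sum (Wilcoxon) or Welch t p-value
#' comparing the groups, plus the PLS-DA VIP score. A metabolite is
#' selected when VIP > `vip_threshold` AND p < `p_threshold`. Group
#' means and sds are reported on the raw intensity scale.
#'
#' @param X samples x metabolites raw intensity matrix.
#' @param y binary group labels.
#' @param vip_threshold VIP cutoff (strict >).
#' @param p_threshold p-value cutoff (strict <).
#' @param test `"wilcoxon"` (default) or `"welch"`.
#' @param log_transform log10-transform intensities before PLS-DA
#'   standardization (ranks are unaffected).
#' @param n_components PLS components for the VIP computation.
#' @return data.frame (class `differential_table`) with one row per
#'   metabolite: group means/sds, `p_value`, `vip`, `selected`; sorted
#'   by p-value.
#' @export
differential_metabolites <- function(X, y, vip_threshold = 1,
                                     p_threshold = 0.05,
                                     test = c("wilcoxon", "welch"),
                                     log_transform = TRUE,
                                     n_components = 2) {
  test <- match.arg(test)
  X <- as.matrix(X)
  y <- as.factor(y)
  if (nlevels(droplevels(y)) != 2) stop("need exactly 2 groups")
  g2 <- levels(y)[2]; g1 <- levels(y)[1]
  Xm <- if (log_transform) log10(pmax(X, .Machine$double.xmin)) else X
  vip <- plsda_vip(Xm, y, n_components = n_components)
  pv <- apply(X, 2, function(v) {
    if (test == "wilcoxon") {
      suppressWarnings(stats::wilcox.test(v[y == g1], v[y == g2])$p.value)
    } else {
      stats::t.test(v[y == g1], v[y == g2])$p.value
    }
  })
  out <- data.frame(
    metabolite_id = colnames(X),
    mean_1 = colMeans(X[y == g1, , drop = FALSE]),
    sd_1 = apply(X[y == g1, , drop = FALSE], 2, stats::sd),
    mean_2 = colMeans(X[y == g2, , drop = FALSE]),
    sd_2 = apply(X[y == g2, , drop = FALSE], 2, stats::sd),
    p_value = pv,
    vip = vip,
    row.names = NULL
  )
  names(out)[2:5] <- c(paste0("mean_", g1), paste0("sd_", g1),
                       paste0("mean_", g2), paste0("sd_", g2))
  out$selected <- out$vip > vip_threshold & out$p_value < p_threshold
  out <- out[order(out$p_value), ]
  rownames(out) <- NULL
  class(out) <- c("differential_table", "data.frame")
  out
}

# Ridge-penalized logistic regression by IRLS; fallback for separated
# data where plain maximum likelihood diverges.
ridge_logistic <- function(X, y01, lambda = 0.5, max_iter = 100) {
  X1 <- cbind(`(Intercept)` = 1, X)
  beta <- rep(0, ncol(X1))
  pen <- diag(c(0, rep(lambda, ncol(X))), ncol(X1))
  for (i in seq_len(max_iter)) {
    eta <- as.numeric(X1 %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-8)
    z <- eta + (y01 - mu) / w
    beta_new <- solve(crossprod(X1 * sqrt(w)) + pen,
                      crossprod(X1, w * z))
    if (max(abs(beta_new - beta)) < 1e-8) { beta <- beta_new; break }
    beta <- beta_new
  }
  as.numeric(beta)
}

#' Build a metabolite biomarker panel by stepwise logistic regression
#'
#' Starting from the empty (intercept-only) model, performs
#' bidirectional stepwise selection by AIC over the candidate
#' metabolites and refits the final panel by maximum likelihood. The
#' panel score is the linear predictor; its in-sample AUC, a
#' leave-one-out AUC (refitting the fixed panel without each sample),
#' and each member's single-marker AUC are reported, all oriented to
#' \[0.5, 1\].
#'
#' @param X samples x metabolites raw intensity matrix.
#' @param y binary group labels.
#' @param candidates metabolite ids to search over (default: all columns
#'   of `X`); typically the selected rows of a
#'   [differential_metabolites()] table.
#' @param log_transform log10 + z-standardize features before modelling.
#' @return list of class `biomarker_panel`: `members`, `coefficients`
#'   (named, incl. intercept), `panel_auc`, `loo_auc`, `single_aucs`,
#'   `scores`, `ridge_fallback` flag.
#' @export
stepwise_logistic <- function(X, y, candidates = NULL,
                              log_transform = TRUE) {
  X <- as.matrix(X)
  if (is.null(candidates)) candidates <- colnames(X)
  if (length(candidates) < 2) stop("need at least 2 candidate metabolites")
  y01 <- binarize_labels(y)
  Z <- X[, candidates, drop = FALSE]
  if (log_transform) Z <- log10(pmax(Z, .Machine$double.xmin))
  Z <- scale(Z)
  df <- data.frame(.y = y01, Z, check.names = FALSE)

  null_fit <- stats::glm(.y ~ 1, family = stats::binomial(), data = df)
  upper <- stats::reformulate(sprintf("`%s`", candidates), response = ".y")
  sel_fit <- suppressWarnings(
    stats::step(null_fit, scope = list(lower = ~1, upper = upper),
                direction = "both", trace = 0)
  )
  members <- setdiff(all.vars(stats::formula(sel_fit)), ".y")

  ridge_fallback <- FALSE
  if (length(members) == 0) {
    coefs <- stats::coef(null_fit)
    scores <- rep(0, nrow(Z))
  } else {
    fit <- suppressWarnings(
      stats::glm(stats::reformulate(sprintf("`%s`", members),
                                    response = ".y"),
                 family = stats::binomial(), data = df)
    )
    mu <- stats::fitted(fit)
    separated <- !fit$converged || any(mu > 1 - 1e-8) || any(mu < 1e-8)
    if (separated) {
      ridge_fallback <- TRUE
      beta <- ridge_logistic(Z[, members, drop = FALSE], y01)
      coefs <- stats::setNames(beta, c("(Intercept)", members))
      scores <- as.numeric(cbind(1, Z[, members, drop = FALSE]) %*% beta)
    } else {
      coefs <- stats::coef(fit)
      names(coefs) <- gsub("`", "", names(coefs))
      scores <- as.numeric(stats::predict(fit, type = "link"))
    }
  }

  orient <- function(a) max(a, 1 - a)
  panel_auc <- if (length(members)) orient(roc_auc(scores, y01)) else 0.5
  single_aucs <- vapply(members, function(mb) {
    orient(roc_auc(Z[, mb], y01))
  }, numeric(1))

  loo_auc <- NA_real_
  if (length(members)) {
    loo_scores <- vapply(seq_len(nrow(Z)), function(i) {
      fit_i <- tryCatch(suppressWarnings(
        stats::glm(stats::reformulate(sprintf("`%s`", members),
                                      response = ".y"),
                   family = stats::binomial(), data = df[-i, ])),
        error = function(e) NULL)
      if (is.null(fit_i)) return(NA_real_)
      as.numeric(stats::predict(fit_i, newdata = df[i, , drop = FALSE]))
    }, numeric(1))
    if (!anyNA(loo_scores)) loo_auc <- orient(roc_auc(loo_scores, y01))
  }

  structure(list(members = members,
                 coefficients = coefs,
                 panel_auc = panel_auc,
                 loo_auc = loo_auc,
                 single_aucs = single_aucs,
                 scores = scores,
                 ridge_fallback = ridge_fallback),
            class = "biomarker_panel")
}

#' @export
print.biomarker_panel <- function(x, ...) {
  cat("biomarker panel:", if (length(x$members))
    paste(x$members, collapse = ", ") else "(empty)", "\n")
  cat(sprintf("  panel AUC (in-sample): %.4f  leave-one-out: %s\n",
              x$panel_auc,
              ifelse(is.na(x$loo_auc), "NA", sprintf("%.4f", x$loo_auc))))
  if (length(x$single_aucs)) {
    cat("  single-marker AUCs:\n")
    for (mname in names(x$single_aucs)) {
      cat(sprintf("    %-20s %.4f\n", mname, x$single_aucs[[mname]]))
    }
  }
  invisible(x)
}

#' Area under the ROC curve
#'
#' Mann-Whitney AUC: the probability that a random positive sample
#' scores above a random negative one, counting ties as 1/2.
#'
#' @param scores numeric classifier scores.
#' @param labels binary labels (factor second level / TRUE / larger
#'   value = positive class).
#' @return AUC in \[0, 1\] (not orientation-flipped).
#' @export
roc_auc <- function(scores, labels) {
  y01 <- binarize_labels(labels)
  n1 <- sum(y01 == 1)
  n0 <- sum(y01 == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[y01 == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve coordinates
#'
#' @param scores numeric classifier scores.
#' @param labels binary labels (see [roc_auc()]).
#' @return data.frame of `threshold`, `fpr`, `tpr`, from (1,1) to (0,0).
#' @export
roc_curve <- function(scores, labels) {
  y01 <- binarize_labels(labels)
  th <- c(-Inf, sort(unique(scores)), Inf)
  coords <- t(vapply(th, function(t0) {
    pred <- scores > t0
    c(fpr = sum(pred & y01 == 0) / sum(y01 == 0),
      tpr = sum(pred & y01 == 1) / sum(y01 == 1))
  }, numeric(2)))
  data.frame(threshold = th, fpr = coords[, "fpr"], tpr = coords[, "tpr"])
}

#' Spearman correlation grid between metabolites and taxa
#'
#' Covariate-adjusted Spearman rank correlations for every
#' (metabolite, taxon) pair, BH-adjusted within the grid; the
#' statistics behind a differential-metabolite vs differential-taxa
#' heatmap.
#'
#' @param metabolites samples x metabolites matrix (raw intensities).
#' @param taxa a [taxa_table()] or samples x taxa abundance matrix.
#' @param covariates optional covariate data.frame (rownames = sample
#'   ids).
#' @return data.frame with `metabolite_id`, `taxon_id`, `rho`,
#'   `p_value`, `q_value`.
#' @export
metabolite_taxa_heatmap_stats <- function(metabolites, taxa,
                                          covariates = NULL) {
  M <- as.matrix(metabolites)
  Tm <- if (inherits(taxa, "taxa_table")) taxa$abundance else as.matrix(taxa)
  ids <- sort(intersect(rownames(M), rownames(Tm)))
  if (length(ids) < 10) stop("fewer than 10 overlapping samples")
  M <- M[ids, , drop = FALSE]
  Tm <- Tm[ids, , drop = FALSE]
  cov_df <- align_covariates(covariates, ids)
  n <- length(ids)
  k <- n_covariate_cols(cov_df)
  srr <- function(v) {
    r <- residualize(rank(v), cov_df)
    s <- stats::sd(r)
    if (s == 0) rep(NA_real_, length(r)) else r / s
  }
  Rm <- apply(M, 2, srr)
  Rt <- apply(Tm, 2, srr)
  rho <- crossprod(Rm, Rt) / (n - 1)  # metabolites x taxa
  tt <- t_from_cor(rho, n - k)
  p <- 2 * stats::pt(-abs(tt), df = n - 2 - k)
  out <- data.frame(
    metabolite_id = rep(colnames(M), times = ncol(Tm)),
    taxon_id = rep(colnames(Tm), each = ncol(M)),
    rho = as.numeric(rho),
    p_value = as.numeric(p),
    row.names = NULL
  )
  out$q_value <- bh_adjust(out$p_value)
  out
}
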
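#' Rarefy a count table to a common sequencing depth
#'
#' Randomly subsamples each sample's reads without replacement so that
#' every sample ends up with exactly `depth` reads, removing
#' sequencing-effort bias before diversity comparisons.
#'
#' @param x a [taxa_table()] holding counts.
#' @param depth target depth (reads per sample).
#' @param seed integer seed for the subsampling.
#' @return a `taxa_table` whose rows each sum to exactly `depth`.
#' @export
rarefy <- function(x, depth, seed = 1L) {
  stopifnot(inherits(x, "taxa_table"))
  m <- x$abundance
  if (any(m != floor(m))) {
    stop("rarefy() needs integer counts, not relative abundances")
  }
  totals <- rowSums(m)
  short <- totals < depth
  if (any(short)) {
    stop("sample total below rarefaction depth ", depth, ": ",
         paste(sprintf("%s (%d)", rownames(m)[short], totals[short]),
               collapse = ", "))
  }
  set.seed(seed)
  x$abundance <- vegan::rrarefy(m, depth)
  x
}

#' Filter taxa on mean relative abundance and prevalence
#'
#' Keeps taxa whose mean relative abundance across samples exceeds
#' `min_mean_relabund` and that are detected (non-zero) in more than
#' `min_prevalence` of samples. Both rules are strict inequalities.
#' Defaults correspond to the common 0.05% abundance / 5% prevalence
#' screen applied before association testing.
#'
#' @param x a [taxa_table()].
#' @param min_mean_relabund minimum mean relative abundance (proportion).
#' @param min_prevalence minimum detection fraction across samples.
#' @return the filtered `taxa_table` (column order preserved).
#' @export
filter_taxa <- function(x, min_mean_relabund = 5e-4, min_prevalence = 0.05) {
  stopifnot(inherits(x, "taxa_table"))
  prop <- as_proportions(x)
  mean_ra <- colMeans(prop)
  prev <- colMeans(x$abundance > 0)
  keep <- mean_ra > min_mean_relabund & prev > min_prevalence
  if (!any(keep)) {
    warning("no taxa pass the abundance/prevalence filter")
  }
  x$abundance <- x$abundance[, keep, drop = FALSE]
  if (!is.null(x$taxonomy)) {
    x$taxonomy <- x$taxonomy[intersect(names(x$taxonomy),
                                       colnames(x$abundance))]
  }
  x
}

#' Shannon diversity of one sample
#'
#' @param counts non-negative abundance vector for one sample, with at
#'   least one positive entry.
#' @param base logarithm base; the default 2 reports the index in bits.
#' @return Shannon entropy H = -sum p_i log(p_i).
#' @export
shannon <- function(counts, base = 2) {
  if (any(counts < 0)) stop("negative abundances")
  tot <- sum(counts)
  if (tot == 0) stop("all-zero sample: Shannon index undefined")
  p <- counts[counts > 0] / tot
  -sum(p * log(p)) / log(base)
}

#' Number of observed features in one sample
#'
#' @param counts non-negative abundance vector.
#' @return number of taxa with abundance > 0.
#' @export
observed_features <- function(counts) {
  if (any(counts < 0)) stop("negative abundances")
  sum(counts > 0)
}

#' Per-sample alpha-diversity summary
#'
#' @param x a [taxa_table()].
#' @param base logarithm base for the Shannon index.
#' @return data.frame with `sample_id`, `observed_features`, `shannon`.
#' @export
alpha_diversity <- function(x, base = 2) {
  stopifnot(inherits(x, "taxa_table"))
  m <- x$abundance
  data.frame(
    sample_id = rownames(m),
    observed_features = apply(m, 1, observed_features),
    shannon = apply(m, 1, shannon, base = base),
    row.names = NULL
  )
}

#' Bray-Curtis dissimilarity matrix
#'
#' @param x a [taxa_table()] or a samples x taxa matrix with at least two
#'   samples.
#' @return a `dist` object of pairwise Bray-Curtis dissimilarities.
#' @export
bray_curtis <- function(x) {
  m <- if (inherits(x, "taxa_table")) x$abundance else as.matrix(x)
  if (nrow(m) < 2) stop("need at least 2 samples")
  if (sum(rowSums(m) == 0) >= 2) {
    stop("Bray-Curtis undefined for a pair of all-zero samples: ",
         paste(rownames(m)[rowSums(m) == 0], collapse = ", "))
  }
  vegan::vegdist(m, method = "bray")
}

#' Principal-coordinates analysis of a dissimilarity matrix
#'
#' Classical metric scaling: eigendecomposition of the double-centred
#' Gram matrix. Axes are ordered by decreasing eigenvalue; axes with
#' non-positive eigenvalues are excluded from the returned coordinates
#' but the full eigenvalue spectrum is reported.
#'
#' @param d a `dist` object or symmetric zero-diagonal matrix.
#' @param k number of coordinate axes to return.
#' @return list with `points` (samples x k' coordinates, k' <= k limited
#'   to positive eigenvalues), `eig` (all eigenvalues) and
#'   `eig_fraction` (positive eigenvalues as fractions of their sum).
#' @export
pcoa <- function(d, k = 2) {
  if (!inherits(d, "dist")) {
    d <- as.matrix(d)
    if (!isSymmetric(unname(d), tol = 1e-8)) {
      stop("dissimilarity matrix must be symmetric")
    }
    if (any(abs(diag(d)) > 1e-8)) {
      stop("dissimilarity matrix must have a zero diagonal")
    }
    d <- stats::as.dist(d)
  }
  n <- attr(d, "Size")
  fit <- stats::cmdscale(d, k = min(k, n - 1), eig = TRUE)
  eig <- fit$eig
  pos <- eig[eig > sqrt(.Machine$double.eps)]
  pts <- fit$points
  keep <- seq_len(min(ncol(pts), length(pos)))
  list(points = pts[, keep, drop = FALSE],
       eig = eig,
       eig_fraction = pos / sum(pos))
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test of whether between-group dissimilarities
#' exceed within-group dissimilarities. The statistic is
#' R = (mean between-group rank - mean within-group rank) / (M/2), with
#' M = n(n-1)/2 pairs and average ranks on ties, so R lies in \[-1, 1\].
#' The p-value uses the add-one permutation estimator
#' p = (1 + #\{R* >= R\}) / (1 + n_perm).
#'
#' @param d a `dist` object or symmetric dissimilarity matrix.
#' @param groups group label per sample; every group needs >= 2 samples.
#' @param n_perm number of label permutations.
#' @param seed integer seed for the permutations.
#' @return list with `statistic` (R), `p_value`, `n_perm`.
#' @export
anosim_test <- function(d, groups, n_perm = 999, seed = 1L) {
  if (!inherits(d, "dist")) {
    d <- stats::as.dist(as.matrix(d))
  }
  n <- attr(d, "Size")
  groups <- as.factor(groups)
  if (length(groups) != n) stop("one group label per sample required")
  if (nlevels(droplevels(groups)) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs at least 2 samples")
  rk <- rank(as.vector(d))  # average ranks on ties
  M <- n * (n - 1) / 2
  # within[p] is TRUE when pair p joins two samples of one group
  pair_within <- function(g) {
    gm <- outer(g, g, "==")
    gm[lower.tri(gm)]
  }
  r_stat <- function(within) {
    (mean(rk[!within]) - mean(rk[within])) / (M / 2)
  }
  obs <- r_stat(pair_within(groups))
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) {
    r_stat(pair_within(sample(groups)))
  }, numeric(1))
  p <- (1 + sum(perm >= obs)) / (1 + n_perm)
  list(statistic = obs, p_value = p, n_perm = n_perm)
}
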
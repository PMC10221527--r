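#' Describe an implanted taxon-to-metabolite effect
#'
#' The generative counterpart of the two-part model: a taxon can move a
#' metabolite through its detection status (`binary_effect`, the mean
#' shift of log-intensity when the taxon is present, in residual-sd
#' units) and/or through its abundance among detected samples
#' (`quant_effect`, slope per sd of log abundance).
#'
#' @param taxon index of the affected taxon.
#' @param metabolite index of the affected metabolite.
#' @param binary_effect mean shift of log-intensity when present.
#' @param quant_effect slope on standardized log abundance (present
#'   samples only).
#' @param locations gut locations in which the effect acts.
#' @return a list of class `implanted_effect`.
#' @export
implanted_effect <- function(taxon, metabolite, binary_effect = 0,
                             quant_effect = 0,
                             locations = c("ileum", "cecum", "faeces")) {
  if (binary_effect == 0 && quant_effect == 0) {
    stop("at least one of binary_effect, quant_effect must be nonzero")
  }
  locations <- match.arg(locations, several.ok = TRUE)
  structure(list(taxon = as.integer(taxon),
                 metabolite = as.integer(metabolite),
                 binary_effect = binary_effect,
                 quant_effect = quant_effect,
                 locations = locations),
            class = "implanted_effect")
}

#' Configure a synthetic cohort
#'
#' Defines the generative model for an animal cohort in which every
#' animal contributes gut microbiota samples at each location and one
#' serum metabolome sample: zero-inflated log-normal taxon abundances
#' with location-specific prevalence profiles, log-normal metabolite
#' intensities with sex/batch covariate shifts and injection-order
#' drift, pooled-QC replicate injections, implanted taxon-to-metabolite
#' effects, and a binary fatness label driven by designated metabolites.
#'
#' @param n_samples animals per cohort (each sampled at every location).
#' @param n_taxa taxa per location.
#' @param n_metabolites serum metabolite features.
#' @param prevalence_range range from which per-taxon detection
#'   probabilities are drawn, per location (recycled if a single pair).
#' @param taxon_logmean_sd sd of per-taxon log-abundance means and of
#'   the log-abundance draws themselves.
#' @param effect_table list of [implanted_effect()] objects.
#' @param covariate_effects named vector `c(sex = , batch = )`: additive
#'   shifts of log-intensity for the second sex level and per batch.
#' @param qc_every one pooled-QC injection every `qc_every` study
#'   injections (must be >= 2).
#' @param drift_slope additive drift of log-intensity per injection
#'   position (log-linear multiplicative drift).
#' @param noise_sd residual sd of metabolite log-intensity.
#' @param qc_noise_sd replicate noise sd of QC log-intensity.
#' @param fatness_effects named numeric vector mapping metabolite index
#'   to its signed coefficient in the logistic fatness model (default:
#'   four markers).
#' @param locations which gut locations to simulate.
#' @param n_batches number of slaughter batches.
#' @param seed integer seed; the same seed and config reproduce the
#'   cohort exactly.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 300, n_taxa = 50, n_metabolites = 20,
                       prevalence_range = c(0.2, 0.9),
                       taxon_logmean_sd = 1,
                       effect_table = list(),
                       covariate_effects = c(sex = 0.3, batch = 0.3),
                       qc_every = 10,
                       drift_slope = 0,
                       noise_sd = 1,
                       qc_noise_sd = 0.05,
                       fatness_effects = c("1" = 1.5, "2" = 1.5,
                                           "3" = -1.5, "4" = -1.5),
                       locations = c("ileum", "cecum", "faeces"),
                       n_batches = 3,
                       seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              n_taxa = as.integer(n_taxa),
              n_metabolites = as.integer(n_metabolites),
              prevalence_range = prevalence_range,
              taxon_logmean_sd = taxon_logmean_sd,
              effect_table = effect_table,
              covariate_effects = covariate_effects,
              qc_every = as.integer(qc_every),
              drift_slope = drift_slope,
              noise_sd = noise_sd,
              qc_noise_sd = qc_noise_sd,
              fatness_effects = fatness_effects,
              locations = match.arg(locations, several.ok = TRUE),
              n_batches = as.integer(n_batches),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_samples <= 0 || n_taxa <= 0 || n_metabolites <= 0 ||
        n_batches <= 0) {
      stop("all counts must be positive")
    }
    if (any(prevalence_range <= 0) || any(prevalence_range >= 1)) {
      stop("prevalence bounds must lie strictly in (0, 1)")
    }
    if (qc_every < 2) stop("qc_every must be >= 2")
    for (e in effect_table) {
      if (e$taxon < 1 || e$taxon > n_taxa) {
        stop("effect refers to out-of-range taxon index ", e$taxon)
      }
      if (e$metabolite < 1 || e$metabolite > n_metabolites) {
        stop("effect refers to out-of-range metabolite index ",
             e$metabolite)
      }
    }
    if (!is.null(fatness_effects) && length(fatness_effects)) {
      fm <- as.integer(names(fatness_effects))
      if (any(is.na(fm)) || any(fm < 1) || any(fm > n_metabolites)) {
        stop("fatness_effects indices out of range")
      }
    }
  })
  invisible(cfg)
}

#' Simulate a complete synthetic cohort
#'
#' Draws, per location, a zero-inflated relative-abundance taxa table
#' (per-taxon Bernoulli presence at a drawn prevalence; log-normal
#' abundance given presence; rows renormalized to sum to 1), then builds
#' the serum metabolite matrix: log-intensity = baseline + sex/batch
#' covariate shifts + implanted taxon effects + drift(injection order) +
#' Gaussian noise, exponentiated. Pooled-QC injections are interleaved
#' every `qc_every` study samples and are replicate draws of the pooled
#' mean subject only to drift and small noise. A binary fatness label is
#' a balanced median split of a logistic liability on the designated
#' marker metabolites.
#'
#' @param config a [sim_config()].
#' @return list with `taxa` (named list of [taxa_table()] per location),
#'   `metabolites` (a [metabo_matrix()]), `metadata` (data.frame with
#'   `sample_id`, `sex`, `batch`, `fatness_group`, `liability`) and
#'   `truth` (the effect table, returned verbatim).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_samples
  ids <- sprintf("P%04d", seq_len(n))

  # --- covariates -------------------------------------------------------
  sex <- factor(sample(c("F", "M"), n, replace = TRUE))
  batch <- factor(sample(sprintf("B%d", seq_len(config$n_batches)), n,
                         replace = TRUE))
  meta <- data.frame(sample_id = ids, sex = sex, batch = batch,
                     stringsAsFactors = FALSE)

  # --- taxa tables per location ----------------------------------------
  taxa <- list()
  presence <- list()   # per location: n x n_taxa logical
  std_logab <- list()  # per location: standardized log abundance, 0 if absent
  for (loc in config$locations) {
    prev <- stats::runif(config$n_taxa, config$prevalence_range[1],
                         config$prevalence_range[2])
    mu <- stats::rnorm(config$n_taxa, 0, config$taxon_logmean_sd)
    pres <- matrix(stats::rbinom(n * config$n_taxa, 1,
                                 rep(prev, each = n)) == 1,
                   nrow = n)
    la <- matrix(stats::rnorm(n * config$n_taxa, rep(mu, each = n),
                              config$taxon_logmean_sd), nrow = n)
    ab <- ifelse(pres, exp(la), 0)
    # guard against an all-absent sample row (keep rows normalizable)
    empty <- rowSums(ab) == 0
    if (any(empty)) {
      j <- max.col(matrix(stats::runif(sum(empty) * config$n_taxa),
                          ncol = config$n_taxa))
      ab[cbind(which(empty), j)] <- exp(mu[j])
      pres[cbind(which(empty), j)] <- TRUE
    }
    rel <- sweep(ab, 1, rowSums(ab), "/")
    dimnames(rel) <- list(ids, sprintf("Taxon%03d", seq_len(config$n_taxa)))
    taxa[[loc]] <- taxa_table(rel, location = loc, level = "ASV")
    taxa[[loc]]$drawn_prevalence <- stats::setNames(prev, colnames(rel))
    presence[[loc]] <- pres
    # quantitative effects act through the observable quantity: the
    # standardized log relative abundance among detected samples
    z <- matrix(0, n, config$n_taxa)
    for (j in seq_len(config$n_taxa)) {
      idx <- which(pres[, j])
      if (length(idx) > 1 && stats::sd(log(rel[idx, j])) > 0) {
        z[idx, j] <- as.numeric(scale(log(rel[idx, j])))
      }
    }
    std_logab[[loc]] <- z
  }

  # --- metabolite log-intensities --------------------------------------
  m <- config$n_metabolites
  baseline <- stats::rnorm(m, mean = 6, sd = 0.5)  # log10-ish scale in ln units
  L <- matrix(rep(baseline, each = n), nrow = n)
  ce <- config$covariate_effects
  if (!is.na(ce["sex"]) && ce["sex"] != 0) {
    L <- L + (as.integer(sex) - 1) * ce["sex"]
  }
  if (!is.na(ce["batch"]) && ce["batch"] != 0) {
    L <- L + (as.integer(batch) - 1) * ce["batch"]
  }
  for (e in config$effect_table) {
    for (loc in intersect(e$locations, config$locations)) {
      contrib <- e$binary_effect * presence[[loc]][, e$taxon] +
        e$quant_effect * std_logab[[loc]][, e$taxon]
      L[, e$metabolite] <- L[, e$metabolite] + contrib * config$noise_sd
    }
  }
  noise <- matrix(stats::rnorm(n * m, 0, config$noise_sd), nrow = n)
  L <- L + noise

  # --- injection layout: one QC every qc_every study samples -----------
  n_qc <- max(2L, floor(n / config$qc_every))
  total <- n + n_qc
  qc_pos <- unique(round(seq(1, total, length.out = n_qc)))
  n_qc <- length(qc_pos)
  total <- n + n_qc
  is_qc <- seq_len(total) %in% qc_pos
  order_all <- seq_len(total)
  study_order <- order_all[!is_qc]

  drift <- config$drift_slope * order_all
  log_int <- matrix(NA_real_, total, m)
  log_int[!is_qc, ] <- L + drift[!is_qc]
  pooled <- colMeans(L)
  qc_noise <- matrix(stats::rnorm(n_qc * m, 0, config$qc_noise_sd),
                     nrow = n_qc)
  log_int[is_qc, ] <- matrix(rep(pooled, each = n_qc), nrow = n_qc) +
    drift[is_qc] + qc_noise

  intensity <- exp(log_int)
  rn <- character(total)
  rn[!is_qc] <- ids
  rn[is_qc] <- sprintf("QC%02d", seq_len(n_qc))
  rownames(intensity) <- rn
  colnames(intensity) <- sprintf("Feat%04d", seq_len(m))
  annotation <- data.frame(
    feature_id = colnames(intensity),
    compound = sprintf("compound_%03d", seq_len(m)),
    msi_level = rep_len(c(1, 2), m),
    ion_mode = rep_len(c("positive", "negative"), m),
    stringsAsFactors = FALSE
  )
  metabolites <- metabo_matrix(intensity, injection_order = order_all,
                               is_qc = is_qc, annotation = annotation)

  # --- fatness label ----------------------------------------------------
  fe <- config$fatness_effects
  if (!is.null(fe) && length(fe)) {
    mk <- as.integer(names(fe))
    Z <- scale(L[, mk, drop = FALSE])
    liability <- as.numeric(Z %*% fe) + stats::rlogis(n)
  } else {
    liability <- stats::rlogis(n)
  }
  meta$liability <- liability
  meta$fatness_group <- factor(ifelse(liability > stats::median(liability),
                                      "HFG", "LFG"))

  list(taxa = taxa, metabolites = metabolites, metadata = meta,
       truth = config$effect_table)
}

#' Simulate a two-group fatness cohort with shifted marker metabolites
#'
#' Generates the targeted-metabolome design directly: two balanced
#' groups of animals and log-normal metabolite intensities in which the
#' designated marker features are shifted between groups by
#' `effect_size` residual standard deviations.
#'
#' @param n_per_group animals per group.
#' @param n_metabolites number of metabolite features.
#' @param markers indices of the shifted marker features.
#' @param effect_size between-group shift in residual-sd units.
#' @param noise_sd residual sd of log-intensity.
#' @param seed integer seed.
#' @return list with `X` (samples x features raw intensities), `group`
#'   (factor `HFG`/`LFG`) and `markers`.
#' @export
simulate_fatness_cohort <- function(n_per_group = 15, n_metabolites = 30,
                                    markers = 1:4, effect_size = 1.5,
                                    noise_sd = 0.4, seed = 1L) {
  set.seed(seed)
  n <- 2 * n_per_group
  group <- factor(rep(c("HFG", "LFG"), each = n_per_group))
  baseline <- stats::rnorm(n_metabolites, 6, 0.5)
  L <- matrix(rep(baseline, each = n), nrow = n) +
    matrix(stats::rnorm(n * n_metabolites, 0, noise_sd), nrow = n)
  shift_sign <- rep_len(c(1, -1), length(markers))
  for (k in seq_along(markers)) {
    L[group == "HFG", markers[k]] <- L[group == "HFG", markers[k]] +
      shift_sign[k] * effect_size * noise_sd
  }
  X <- exp(L)
  rownames(X) <- sprintf("P%03d", seq_len(n))
  colnames(X) <- sprintf("Met%03d", seq_len(n_metabolites))
  list(X = X, group = group, markers = colnames(X)[markers])
}

#' Empirical null p-value calibration of the two-part scan
#'
#' Repeatedly simulates effect-free cohorts, runs the two-part
#' association scan on each location, pools the pair-level p-values and
#' reports the fraction below each significance level.
#'
#' @param config a [sim_config()] with an empty `effect_table`.
#' @param n_reps number of replicate cohorts (>= 1).
#' @param alpha significance levels to evaluate.
#' @return list with `fraction` (named vector per alpha), `n_pvalues`,
#'   and `p_values` (invisibly large; pooled vector).
#' @export
simulate_null_pvalues <- function(config, n_reps,
                                  alpha = c(0.01, 0.05, 0.10)) {
  stopifnot(inherits(config, "sim_config"))
  if (length(config$effect_table) > 0) {
    stop("null calibration requires an empty effect_table")
  }
  if (n_reps < 1) stop("n_reps must be >= 1")
  pv <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- config$seed + r - 1L
    sim <- simulate_cohort(cfg)
    ps <- lapply(sim$taxa, function(tt) {
      run_association_scan(tt, sim$metabolites,
                           covariates = sim$metadata[, c("sample_id",
                                                         "sex", "batch")])$p_value
    })
    pv[[r]] <- unlist(ps, use.names = FALSE)
  }
  pooled <- unlist(pv, use.names = FALSE)
  frac <- vapply(alpha, function(a) mean(pooled < a), numeric(1))
  names(frac) <- paste0("alpha_", alpha)
  list(fraction = frac, n_pvalues = length(pooled), p_values = pooled)
}
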
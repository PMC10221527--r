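# Small single-location cohort used across tests.
small_cohort <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_samples = 80, n_taxa = 15, n_metabolites = 8,
         locations = "cecum", seed = seed),
    list(...)
  )
  simulate_cohort(do.call(sim_config, args))
}

sim_covariates <- function(sim) {
  sim$metadata[, c("sample_id", "sex", "batch")]
}

# Random count taxa table for rarefaction/diversity tests.
random_count_table <- function(n = 12, p = 20, min_total = 500, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(n * p, lambda = rep(rgamma(p, 1, 0.02), each = n)),
              nrow = n)
  m[cbind(seq_len(n), sample.int(p, n, replace = TRUE))] <- min_total
  rownames(m) <- sprintf("S%02d", seq_len(n))
  colnames(m) <- sprintf("T%03d", seq_len(p))
  taxa_table(m, location = "faeces", level = "ASV")
}

# Metabolite matrix with explicit drift/noise, for QC-module tests.
drifted_metabo <- function(n_study = 40, n_feat = 6, n_qc = 8,
                           drift_slope = 0, noise_sd = 0,
                           qc_noise_sd = 0, seed = 1) {
  set.seed(seed)
  total <- n_study + n_qc
  qc_pos <- round(seq(1, total, length.out = n_qc))
  is_qc <- seq_len(total) %in% qc_pos
  base <- matrix(rep(exp(rnorm(n_feat, 5, 0.3)), each = total),
                 nrow = total)
  lg <- log(base) + drift_slope * seq_len(total)
  lg[!is_qc, ] <- lg[!is_qc, ] + rnorm(n_study * n_feat, 0, noise_sd)
  lg[is_qc, ] <- lg[is_qc, ] + rnorm(n_qc * n_feat, 0, qc_noise_sd)
  metabo_matrix(exp(lg), injection_order = seq_len(total), is_qc = is_qc)
}

# Independent step-up BH implementation (test oracle).
bh_manual <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  pmin(1, q)[order(o)]
}
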
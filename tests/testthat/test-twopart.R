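test_that("residualization removes covariate effects exactly", {
  set.seed(1)
  n <- 60
  cov <- data.frame(sex = factor(sample(c("F", "M"), n, TRUE)),
                    batch = factor(sample(c("B1", "B2", "B3"), n, TRUE)))
  y <- rnorm(n) + 1.0 * (cov$sex == "M") + 0.5 * as.integer(cov$batch)
  r <- residualize(y, cov)
  expect_equal(mean(r), 0, tolerance = 1e-12)
  # residual is exactly orthogonal to the fitted sex contrast
  sex_num <- as.numeric(cov$sex == "M")
  tstat <- unname(coef(summary(lm(r ~ sex_num)))[2, "t value"])
  expect_lt(abs(tstat), 1e-8)
  # y an exact function of batch leaves a ~0 residual
  y2 <- 2 * as.integer(cov$batch)
  expect_lt(max(abs(residualize(y2, cov))), 1e-10)
  # no covariates: centring only
  expect_equal(residualize(y), y - mean(y))
  # aliased column dropped with a message
  cov$dup <- cov$sex
  expect_message(residualize(y, cov), "aliased")
})

test_that("binary part is calibrated under the null and powered under a shift", {
  set.seed(2)
  n <- 300
  z_null <- replicate(1000, {
    pres <- rbinom(n, 1, 0.5)
    binary_part(rnorm(n), pres)$z
  })
  expect_gt(mean(abs(z_null) > 1.96), 0.03)
  expect_lt(mean(abs(z_null) > 1.96), 0.07)
  # 1-sd shift at n = 300 gives |z| > 10
  pres <- rep(0:1, each = 150)
  y <- rnorm(n, mean = pres)
  expect_gt(abs(binary_part(y, pres)$z), 10 - 4)  # noncentrality ~ 8.7
  expect_gt(binary_part(y, pres)$beta, 0.5)
  # degenerate inputs do not run
  expect_null(binary_part(rep(0, n), pres))          # constant response
  expect_null(binary_part(rnorm(10), c(1, rep(0, 9))))  # class too small
})

test_that("quantitative part matches its closed-form noncentrality", {
  set.seed(3)
  zs <- replicate(200, {
    x <- rnorm(200)
    y <- 0.5 * x + rnorm(200)
    quant_part(y, abundance = 10^x, presence = rep(1, 200))$z
  })
  # slope 0.5 sd/sd with 200 present samples: E|z| ~ 0.447 * sqrt(198)/0.894 ~ 7
  expect_gt(mean(abs(zs)), 6)
  expect_lt(mean(abs(zs)), 8)
  # null z is standard normal
  set.seed(4)
  z0 <- replicate(2000, {
    quant_part(rnorm(80), abundance = 10^rnorm(80),
               presence = rep(1, 80))$z
  })
  ks <- ks.test(z0, "pnorm")
  expect_gt(ks$p.value, 0.01)
  # shared abundance value among present samples: part not run
  expect_null(quant_part(rnorm(30), rep(0.2, 30), rep(1, 30)))
  expect_null(quant_part(rnorm(30), 10^rnorm(30), c(rep(1, 5), rep(0, 25))))
})

test_that("unweighted Z combination matches closed forms", {
  expect_equal(meta_unweighted_z(0, 0)$z_meta, 0)
  expect_equal(meta_unweighted_z(0, 0)$p_value, 1)
  m <- meta_unweighted_z(1.96, 1.96)
  expect_equal(m$z_meta, 2.7719, tolerance = 1e-4)
  expect_lt(abs(m$p_value - 0.005561), 2e-5)
  expect_equal(meta_unweighted_z(2.5, -2.5)$z_meta, 0)
  expect_equal(meta_unweighted_z(2.5, -2.5)$p_value, 1)
  # single-part reduction
  expect_equal(meta_unweighted_z(NA, 3.1)$z_meta, 3.1)
  expect_equal(meta_unweighted_z(-2.2, NA)$z_meta, -2.2)
  expect_error(meta_unweighted_z(NA, NA), "no sub-model")
})

test_that("BH adjustment matches the step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.37), 0.37)
  set.seed(5)
  for (i in 1:10) {
    p <- runif(sample(2:20, 1))^2
    expect_equal(bh_adjust(p), bh_manual(p), tolerance = 1e-12)
  }
})

test_that("association scan agrees with the scalar sub-model functions", {
  sim <- small_cohort(seed = 12, n_samples = 120)
  covs <- sim_covariates(sim)
  scan <- run_association_scan(sim$taxa$cecum, sim$metabolites,
                               covariates = covs)
  ids <- sort(intersect(rownames(sim$taxa$cecum$abundance),
                        rownames(gutlink:::study_intensity(sim$metabolites))))
  prop <- sim$taxa$cecum$abundance[ids, ]
  Y <- gutlink:::study_intensity(sim$metabolites)[ids, ]
  cov_al <- gutlink:::align_covariates(covs, ids)
  set.seed(99)
  for (k in sample(nrow(scan), 6)) {
    row <- scan[k, ]
    y <- residualize(as.numeric(transform_metabolite(Y[, row$metabolite_id])),
                     cov_al)
    pres <- prop[, row$taxon_id] > 0
    if (!is.na(row$z_binary)) {
      expect_equal(binary_part(y, pres)$z, row$z_binary, tolerance = 1e-10)
    }
    if (!is.na(row$z_quant)) {
      expect_equal(quant_part(y, prop[, row$taxon_id], pres)$z,
                   row$z_quant, tolerance = 1e-10)
    }
    zb <- if (is.na(row$z_binary)) NA else row$z_binary
    zq <- if (is.na(row$z_quant)) NA else row$z_quant
    expect_equal(meta_unweighted_z(zb, zq)$z_meta, row$z_meta,
                 tolerance = 1e-10)
    expect_equal(2 * pnorm(-abs(row$z_meta)), row$p_value, tolerance = 1e-12)
  }
  expect_equal(scan$q_value, bh_manual(scan$p_value), tolerance = 1e-12)
})

test_that("association scan is invariant to sample order and intensity scale", {
  sim <- small_cohort(seed = 13, n_samples = 100)
  covs <- sim_covariates(sim)
  scan1 <- run_association_scan(sim$taxa$cecum, sim$metabolites,
                                covariates = covs)
  # shuffle taxa-sample order
  tt <- sim$taxa$cecum
  perm <- sample(nrow(tt$abundance))
  tt$abundance <- tt$abundance[perm, ]
  scan2 <- run_association_scan(tt, sim$metabolites, covariates = covs)
  expect_equal(scan1$z_meta, scan2$z_meta, tolerance = 1e-12)
  # global intensity rescaling is absorbed by the transform
  mm <- sim$metabolites
  mm$intensity <- mm$intensity * 1000
  scan3 <- run_association_scan(sim$taxa$cecum, mm, covariates = covs)
  expect_equal(scan1$z_meta, scan3$z_meta, tolerance = 1e-9)
  # a duplicated metabolite produces identical result rows
  mm2 <- sim$metabolites
  mm2$intensity <- cbind(mm2$intensity,
                         dup = mm2$intensity[, "Feat0001"])
  mm2$annotation <- NULL
  scan4 <- run_association_scan(sim$taxa$cecum, mm2, covariates = covs)
  a <- scan4[scan4$metabolite_id == "Feat0001",
             c("taxon_id", "z_binary", "z_quant", "z_meta")]
  b <- scan4[scan4$metabolite_id == "dup",
             c("taxon_id", "z_binary", "z_quant", "z_meta")]
  b <- b[match(a$taxon_id, b$taxon_id), ]
  expect_equal(a$z_meta, b$z_meta, tolerance = 1e-12)
  # too few overlapping samples is refused
  expect_error(run_association_scan(sim$taxa$cecum, sim$metabolites,
                                    min_overlap = 1e6),
               "overlapping samples")
})

test_that("partial Spearman matches rank-based oracles", {
  x <- seq_len(12)
  expect_equal(spearman_partial(x, x)$rho, 1)
  expect_equal(spearman_partial(-x^2, x)$rho, -1)  # monotone decreasing
  # ties: agree with stats::cor(method = 'spearman') when no covariates
  set.seed(6)
  a <- sample(c(1, 2, 2, 3, 5, 5, 7, 8, 9, 9, 10, 12))
  b <- rnorm(12)
  expect_equal(spearman_partial(b, a)$rho,
               cor(b, a, method = "spearman"), tolerance = 1e-12)
  # p-value approximation matches cor.test's t approximation
  ct <- suppressWarnings(cor.test(b, a, method = "spearman"))
  expect_equal(spearman_partial(b, a)$rho, unname(ct$estimate),
               tolerance = 1e-12)
  expect_error(spearman_partial(rep(1, 12), x), "constant")
  expect_error(spearman_partial(1:5, 1:5), "at least 10")
})

test_that("Spearman validation replicates strong two-part associations", {
  eff <- lapply(1:5, function(k) {
    implanted_effect(k, k, binary_effect = 1.0, quant_effect = 0.8,
                     locations = "cecum")
  })
  sim <- small_cohort(seed = 21, n_samples = 250, n_taxa = 20,
                      n_metabolites = 10, effect_table = eff,
                      fatness_effects = NULL)
  covs <- sim_covariates(sim)
  scan <- run_association_scan(sim$taxa$cecum, sim$metabolites,
                               covariates = covs)
  rep_ <- validate_with_spearman(scan, sim$taxa$cecum, sim$metabolites,
                                 covariates = covs)
  expect_gte(rep_$n_significant, 5)
  expect_gte(rep_$replication_fraction, 0.8)
  # a null cohort has (near) nothing to replicate
  sim0 <- small_cohort(seed = 22, n_samples = 100, fatness_effects = NULL)
  scan0 <- run_association_scan(sim0$taxa$cecum, sim0$metabolites,
                                covariates = sim_covariates(sim0))
  rep0 <- validate_with_spearman(scan0, sim0$taxa$cecum, sim0$metabolites,
                                 covariates = sim_covariates(sim0))
  expect_lte(rep0$n_significant, 2)
})
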
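test_that("rarefaction conserves depth, never creates taxa, errors on short samples", {
  tt <- random_count_table(seed = 4)
  depth <- 400
  # vegan warns because the toy table has tiny counts; irrelevant here
  rr <- suppressWarnings(rarefy(tt, depth, seed = 1))
  expect_true(all(rowSums(rr$abundance) == depth))
  expect_true(all(rr$abundance[tt$abundance == 0] == 0))
  expect_true(all(rr$abundance <= tt$abundance))
  # observed features can only drop under subsampling
  expect_true(all(apply(rr$abundance, 1, observed_features) <=
                    apply(tt$abundance, 1, observed_features)))
  # a sample already exactly at depth is returned unchanged
  one <- taxa_table(matrix(c(3L, 2L, 5L), 1, 3,
                           dimnames = list("s1", c("a", "b", "c"))),
                    location = "ileum")
  expect_equal(suppressWarnings(rarefy(one, 10, seed = 1))$abundance,
               one$abundance)
  expect_error(rarefy(tt, 10^7), "below rarefaction depth")
})

test_that("abundance/prevalence filter keeps exactly the taxa passing both strict rules", {
  # 10 samples x 6 taxa built so exactly 3 taxa pass both rules:
  # mean relative abundance > 0.05% AND detected in > 5% of samples
  m <- matrix(0, 10, 6,
              dimnames = list(sprintf("s%02d", 1:10), paste0("t", 1:6)))
  m[, 1] <- 1000              # abundant, everywhere -> keep
  m[1:3, 2] <- 500            # abundant, 30% prevalence -> keep
  m[1, 3] <- 50               # 10% prevalence, mean ra ~ 0.3% -> keep
  m[1:2, 4] <- c(1, 1)        # mean ra ~ 0.01% -> fail abundance
  m[, 5] <- 0                 # absent -> fail both
  # taxon detected in s7 only would be 10% prevalent; use a separate
  # matrix to exercise the 4-of-100 prevalence failure below
  m[1, 6] <- 2                # mean ra ~ 0.01% -> fail abundance
  tt <- taxa_table(m, location = "cecum")
  kept <- colnames(filter_taxa(tt)$abundance)
  expect_identical(kept, c("t1", "t2", "t3"))
  # prevalence 4% <= 5% is removed even when abundant
  m2 <- matrix(0, 100, 2,
               dimnames = list(sprintf("s%03d", 1:100), c("big", "rare")))
  m2[, 1] <- 100
  m2[1:4, 2] <- 1e5
  tt2 <- taxa_table(m2, location = "cecum")
  expect_identical(colnames(filter_taxa(tt2)$abundance),
                   colnames(m2)[1])
  # idempotence
  f1 <- filter_taxa(tt)
  expect_identical(filter_taxa(f1)$abundance, f1$abundance)
})

test_that("Shannon index and observed features match closed forms", {
  expect_equal(shannon(rep(5, 4)), 2)             # uniform over 4 taxa
  expect_equal(shannon(c(0, 7, 0)), 0)            # single taxon
  expect_equal(shannon(c(1, 1, 2)), 1.5)          # hand-derived
  expect_error(shannon(c(0, 0)), "all-zero")
  expect_equal(observed_features(c(1, 1, 2, 0)), 3)
  expect_equal(observed_features(c(0, 0)), 0)
  # cross-check against vegan on random samples
  set.seed(8)
  for (i in 1:5) {
    v <- rpois(30, 3) + c(1, rep(0, 29))
    expect_equal(shannon(v, base = exp(1)),
                 unname(vegan::diversity(matrix(v, 1))), tolerance = 1e-12)
  }
})

test_that("Bray-Curtis dissimilarity matches its definition", {
  x <- rbind(a = c(1, 1), b = c(1, 3))
  d <- as.matrix(bray_curtis(x))
  expect_equal(d["a", "b"], 1 / 3)
  expect_equal(as.numeric(as.matrix(bray_curtis(rbind(c(2, 5), c(2, 5))))[1, 2]), 0)
  expect_equal(as.numeric(as.matrix(bray_curtis(rbind(c(1, 0), c(0, 9))))[1, 2]), 1)
  # manual formula on a random table
  set.seed(2)
  m <- matrix(runif(5 * 4), 5, 4)
  d2 <- as.matrix(bray_curtis(m))
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(d2[i, j],
                 sum(abs(m[i, ] - m[j, ])) / sum(m[i, ] + m[j, ]),
                 tolerance = 1e-12)
  }
  expect_error(bray_curtis(rbind(c(0, 0), c(0, 0), c(1, 2))), "all-zero")
})

test_that("PCoA reproduces distances from a full-rank embedding", {
  set.seed(11)
  pts <- matrix(rnorm(7 * 3), 7, 3)
  d <- dist(pts)
  fit <- pcoa(d, k = 6)
  d2 <- dist(fit$points)
  expect_equal(as.numeric(d2), as.numeric(d), tolerance = 1e-8)
  # three equidistant points: two equal positive eigenvalues
  deq <- as.dist(matrix(1, 3, 3) - diag(3))
  f3 <- pcoa(deq, k = 2)
  pos <- f3$eig[f3$eig > 1e-10]
  expect_length(pos, 2)
  expect_equal(pos[1], pos[2], tolerance = 1e-10)
  # collinear points: one positive eigenvalue carries all variance
  dl <- dist(matrix(c(0, 1, 2.5, 4), 4, 1))
  fl <- pcoa(dl, k = 3)
  expect_equal(fl$eig_fraction[1], 1, tolerance = 1e-10)
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("ANOSIM matches the exhaustive permutation distribution at n = 6", {
  set.seed(3)
  pts <- matrix(rnorm(6 * 2), 6, 2)
  pts[1:3, ] <- pts[1:3, ] + 1.2
  d <- dist(pts)
  g <- rep(c("A", "B"), each = 3)
  res <- anosim_test(d, g, n_perm = 99999, seed = 1)
  # brute-force oracle over all 20 balanced label assignments
  rk <- rank(as.vector(d))
  M <- 15
  r_of <- function(lab) {
    w <- outer(lab, lab, "==")[lower.tri(matrix(0, 6, 6))]
    (mean(rk[!w]) - mean(rk[w])) / (M / 2)
  }
  combs <- utils::combn(6, 3)
  rs <- apply(combs, 2, function(ix) {
    lab <- rep("B", 6); lab[ix] <- "A"; r_of(lab)
  })
  p_exact <- mean(rs >= res$statistic - 1e-12)
  expect_equal(res$p_value, p_exact, tolerance = 0.02)
  expect_true(res$statistic >= -1 && res$statistic <= 1)
  expect_true(res$p_value > 0 && res$p_value <= 1)
})

test_that("ANOSIM R statistic agrees with vegan and is 1 under perfect separation", {
  set.seed(21)
  pts <- matrix(rnorm(16 * 3), 16, 3)
  g <- rep(c("A", "B"), each = 8)
  pts[g == "A", ] <- pts[g == "A", ] + 0.8
  d <- dist(pts)
  ours <- anosim_test(d, g, n_perm = 199, seed = 2)
  ref <- vegan::anosim(d, g, permutations = 49)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
  # all within-group distances strictly below all between-group ones -> R = 1
  sep <- matrix(c(0, 0, 10, 10, 0.1, 0, 10.1, 10), 4, 2)
  gsep <- c("A", "A", "B", "B")
  expect_equal(anosim_test(dist(sep), gsep, n_perm = 99)$statistic, 1)
  expect_error(anosim_test(d, c("A", rep("B", 15)), 99), "at least 2 samples")
})

test_that("ANOSIM permutation p is calibrated under label exchangeability", {
  set.seed(77)
  rej <- vapply(1:300, function(i) {
    pts <- matrix(rnorm(12 * 2), 12, 2)
    g <- sample(rep(c("A", "B"), each = 6))
    anosim_test(dist(pts), g, n_perm = 99, seed = i)$p_value <= 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
})
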
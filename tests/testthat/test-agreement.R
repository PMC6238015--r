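test_that("Bland-Altman ratio statistics match hand computation", {
  p <- paired_measurements(c(0.9, 1.0, 1.1), c(1, 1, 1))
  ba <- bland_altman_ratio(p)
  expect_equal(ba$mean_ratio, 1.0)
  expect_equal(ba$loa_pct, 19.6, tolerance = 1e-12)
  expect_equal(ba$loa_low, 1 - 1.96 * 0.1)
  expect_equal(ba$loa_high, 1 + 1.96 * 0.1)
  # identity: mean ratio 1, zero-width limits
  q <- paired_measurements(c(2, 3, 4), c(2, 3, 4))
  expect_equal(bland_altman_ratio(q)$loa_pct, 0)
  # ratios are invariant to a common scale and to relabeling
  r <- paired_measurements(2 * c(0.9, 1.0, 1.1), 2 * c(1, 1, 1))
  expect_equal(bland_altman_ratio(r)$loa_pct, ba$loa_pct)
  perm <- paired_measurements(c(1.1, 0.9, 1.0), c(1, 1, 1))
  expect_equal(bland_altman_ratio(perm)$mean_ratio, ba$mean_ratio)
  expect_error(bland_altman_ratio(paired_measurements(1:3, c(1, 0, 2))), "positive")
})

test_that("ICC(2,1) matches the mean-squares oracle on a worked dataset", {
  # classic 6-target x 4-judge reliability dataset
  m <- matrix(c(9, 2, 5, 8,
                6, 1, 3, 2,
                8, 4, 6, 8,
                7, 1, 2, 6,
                10, 5, 6, 9,
                6, 2, 4, 7), nrow = 6, byrow = TRUE)
  # oracle: two-way anova mean squares computed via aov
  d <- data.frame(y = as.vector(m),
                  subj = factor(rep(1:6, 4)),
                  rater = factor(rep(1:4, each = 6)))
  ms <- summary(aov(y ~ subj + rater, data = d))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  n <- 6; k <- 4
  oracle <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  expect_equal(icc(m), oracle, tolerance = 1e-12)
  expect_equal(icc(m), 0.29, tolerance = 0.005)  # its published value
})

test_that("ICC behaves as an absolute-agreement coefficient", {
  set.seed(10)
  x <- rnorm(20, 10, 2)
  y <- x + rnorm(20, 0, 0.5)
  p <- paired_measurements(y, x)
  expect_equal(icc(paired_measurements(x, x)), 1)
  base_icc <- icc(p)
  biased <- paired_measurements(y + 5, x)
  expect_lt(icc(biased), base_icc)  # constant bias lowers absolute agreement
  expect_gt(base_icc, 0.9)
  expect_error(icc(paired_measurements(1:2, 2:3)), "3 subjects")
})

test_that("Wilcoxon paired p values match 2^n enumeration", {
  set.seed(6)
  for (n in c(8, 10, 12)) {
    d <- round(rnorm(n, 0.2, 1), 6)
    d <- d[d != 0]
    while (anyDuplicated(abs(d))) d <- d + 1e-4 * seq_along(d)
    x <- rnorm(length(d))
    p <- paired_measurements(x + d, x)
    for (alt in c("two_sided", "greater", "less")) {
      expect_equal(wilcoxon_paired(p, alt), enumerate_signed_rank_p(d, alt),
                   tolerance = 1e-10)
    }
  }
})

test_that("Wilcoxon edge cases: all-positive n=6 one-tailed, symmetric null", {
  x <- c(1, 2, 3, 4, 5, 6)
  p <- paired_measurements(x + c(0.5, 0.7, 1.1, 0.2, 0.9, 1.3), x)
  expect_equal(wilcoxon_paired(p, "greater"), 1 / 64)
  # perfectly symmetric differences: two-sided p near 1
  d <- c(-5, -4, -3, -2, -1, 1, 2, 3, 4, 5) + 1e-3 * (1:10)
  psym <- paired_measurements(d, rep(0, 10))
  expect_gt(wilcoxon_paired(psym, "two_sided"), 0.8)
  expect_error(wilcoxon_paired(paired_measurements(1:3, 1:3)), "zero")
})

test_that("one-sided and two-sided exact Wilcoxon p values are consistent", {
  set.seed(8)
  for (i in 1:10) {
    d <- rnorm(9)
    while (anyDuplicated(abs(d)) || any(d == 0)) d <- rnorm(9)
    p <- paired_measurements(d, rep(0, 9))
    p2 <- wilcoxon_paired(p, "two_sided")
    p1 <- min(wilcoxon_paired(p, "greater"), wilcoxon_paired(p, "less"))
    expect_lte(p2, 2 * p1 + 1e-12)
  }
})

test_that("Pearson correlation matches the covariance formula", {
  p <- paired_measurements(2 * (1:10), 1:10)
  expect_equal(pearson(p)$r, 1)
  expect_equal(pearson(paired_measurements(-(1:10), 1:10))$r, -1)
  set.seed(3)
  x <- rnorm(30); y <- 0.5 * x + rnorm(30)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson(paired_measurements(y, x))$r, r_oracle, tolerance = 1e-12)
  expect_error(pearson(paired_measurements(rep(1, 5), 1:5)), "variance")
})

test_that("response deltas are fractional changes at the baseline maximum voxel", {
  d3 <- c(4, 4, 4)
  mask <- array(TRUE, d3)
  ki0 <- array(0.01, d3); ki0[2, 2, 2] <- 0.05
  suv0 <- array(1, d3); suv0[2, 2, 2] <- 8
  ki1 <- ki0; ki1[2, 2, 2] <- 0.04
  suv1 <- suv0; suv1[2, 2, 2] <- 6
  b <- list(ki = ki0, suv = suv0, mask = mask)
  f <- list(ki = ki1, suv = suv1, mask = mask)
  d <- delta_response(b, f)
  expect_equal(d$delta_ki_max, -0.20)
  expect_equal(d$delta_suv_max, -0.25)
  # no change and scale invariance
  expect_equal(delta_response(b, b)$delta_ki_max, 0)
  b2 <- list(ki = 2 * ki0, suv = 2 * suv0, mask = mask)
  f2 <- list(ki = 2 * ki1, suv = 2 * suv1, mask = mask)
  expect_equal(delta_response(b2, f2)$delta_ki_max, -0.20)
  zero <- list(ki = array(0, d3), suv = suv0, mask = mask)
  expect_error(delta_response(zero, f), "zero")
})

test_that("convergence analysis: zero variance gives zero CV; CV shrinks with draws", {
  meas0 <- noiseless_meas(0.04, 0.3)
  conv0 <- convergence_analysis(meas0, draws_list = c(10, 100), repeats = 3, seed = 1)
  expect_equal(conv0$ki_cv, c(0, 0))
  expect_error(convergence_analysis(meas0, repeats = 1), "repeats")
  # Spearman correlation between n and CV is negative on average
  meas <- noiseless_meas(0.04, 0.3)
  meas$c_fdg_var <- (0.08 * meas$c_fdg_mean)^2
  meas$c_p_var <- (0.03 * meas$c_p_mean)^2
  rho <- vapply(1:20, function(r) {
    cv <- convergence_analysis(meas, draws_list = c(10, 100, 1000),
                               repeats = 5, seed = 100 + r)$ki_cv
    cor(c(10, 100, 1000), cv, method = "spearman")
  }, 0)
  expect_lte(mean(rho), 0)
})

test_that("contrast ratio is max-lesion over mean-necrosis and scale invariant", {
  d3 <- c(4, 4, 2)
  img <- array(100, d3)
  lesion <- array(FALSE, d3); lesion[1:3, 1:3, ] <- TRUE
  nec <- array(FALSE, d3); nec[2, 2, ] <- TRUE
  img[1, 1, 1] <- 570
  expect_equal(contrast_ratio(img, lesion, nec), 5.7)
  expect_equal(contrast_ratio(3 * img, lesion, nec), 5.7)
  expect_equal(contrast_ratio(array(1, d3), lesion, nec), 1)
  expect_error(contrast_ratio(array(0, d3), lesion, nec), "zero")
})

test_that("image normalization supports slice-count and background conventions", {
  img <- array(runif(32, 1, 5), c(4, 4, 2))
  ns <- normalize_image(img, "slice_counts")
  expect_equal(sum(ns[, , 1]), 1)
  expect_equal(sum(ns[, , 2]), 1)
  bg <- array(FALSE, c(4, 4, 2)); bg[1, , ] <- TRUE
  nb <- normalize_image(img, "background", background_mask = bg)
  expect_equal(mean(nb[bg]), 1)
})
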
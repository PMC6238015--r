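test_that("Patlak fit recovers noiseless kinetics exactly", {
  meas <- noiseless_meas(ki = 0.05, vp = 0.3)
  est <- patlak_fit(meas)
  expect_equal(est$ki, 0.05, tolerance = 1e-10)
  expect_equal(est$vp, 0.3, tolerance = 1e-10)
  # null kinetics give the null estimate
  z <- noiseless_meas(0, 0)
  ez <- patlak_fit(z)
  expect_equal(abs(ez$ki) + abs(ez$vp), 0, tolerance = 1e-12)
})

test_that("two time points give a saturated, zero-residual Patlak fit", {
  fn <- fix_input_fn()
  tt <- c(82, 90)
  cp <- evaluate_cp(fn, tt)
  icp <- integrate_cp(fn, tt)
  c_fdg <- c(15000, 16500)  # arbitrary, not on the model
  meas <- measurement_set(tt, c_fdg, c(0, 0), cp, c(0, 0), icp)
  est <- patlak_fit(meas)
  expect_equal(est$ki * icp + est$vp * cp, c_fdg, tolerance = 1e-8)
})

test_that("collinear Patlak design is rejected", {
  tt <- c(82, 86, 90)
  icp <- c(100, 200, 300)
  meas <- measurement_set(tt, c(1, 2, 3), c(0, 0, 0), icp * 0.01, c(0, 0, 0), icp)
  expect_error(patlak_fit(meas), "collinear")
})

test_that("Hunter bound is the first-point quotient and dominates Patlak Ki", {
  tt <- c(10, 20)
  meas <- measurement_set(tt, c(800, 900), c(0, 0), c(100, 90), c(0, 0), c(10000, 11000))
  expect_equal(hunter_k(meas), 0.08)
  # vp = 0: Hunter equals the true ki exactly
  m0 <- noiseless_meas(ki = 0.04, vp = 0)
  expect_equal(hunter_k(m0), 0.04, tolerance = 1e-12)
  # vp > 0: strict positive bias (the known Hunter overestimation)
  for (vp in c(0.1, 0.3, 0.6)) {
    m <- noiseless_meas(ki = 0.04, vp = vp)
    expect_gt(hunter_k(m), patlak_fit(m)$ki)
  }
})

test_that("constrained solver equals OLS when the optimum is interior", {
  meas <- noiseless_meas(ki = 0.03, vp = 0.4)
  kh <- hunter_k(meas)
  sol <- solve_constrained(meas$c_fdg_mean, meas$c_p_mean, meas$c_p_integral, kh)
  expect_equal(sol$ki, 0.03, tolerance = 1e-9)
  expect_equal(sol$vp, 0.4, tolerance = 1e-9)
})

test_that("constrained solver activates the Hunter bound (KKT by hand)", {
  # true ki above the imposed bound: x pins at kh and y is the
  # least-squares solution given x = kh
  meas <- noiseless_meas(ki = 0.05, vp = 0.3)
  kh <- 0.04
  sol <- solve_constrained(meas$c_fdg_mean, meas$c_p_mean, meas$c_p_integral, kh)
  expect_equal(sol$ki, kh)
  y_given_x <- sum(meas$c_p_mean * (meas$c_fdg_mean - kh * meas$c_p_integral)) /
    sum(meas$c_p_mean^2)
  expect_equal(sol$vp, max(y_given_x, 0), tolerance = 1e-9)
  # degenerate all-zero regressors return (0, 0) with a flag
  d <- solve_constrained(c(1, 1), c(0, 0), c(0, 0), 1)
  expect_true(d$degenerate)
  expect_equal(c(d$ki, d$vp), c(0, 0))
})

test_that("constrained solver matches a 400x400 grid-search oracle", {
  set.seed(77)
  for (i in 1:50) {
    K <- sample(3:6, 1)
    icp <- sort(runif(K, 50, 500))
    cp <- runif(K, 10, 100)
    ki_true <- runif(1, 0, 0.2)
    vp_true <- runif(1, 0, 2)
    c_fdg <- ki_true * icp + vp_true * cp + rnorm(K, 0, 5)
    c_fdg <- pmax(c_fdg, 0)
    kh <- runif(1, 0.02, 0.3)
    sol <- solve_constrained(c_fdg, cp, icp, kh)
    y_max <- max(2 * vp_true, 2 * sol$vp, 1)
    g <- grid_solve(c_fdg, cp, icp, kh, y_max)
    check_grid_match(sol, g, c_fdg, cp, icp, kh, y_max)
  }
})

test_that("Monte-Carlo estimate with zero variances is the deterministic solution", {
  meas <- noiseless_meas(ki = 0.03, vp = 0.4)
  est <- monte_carlo_estimate(meas, n_draws = 50, seed = 1)
  kh <- hunter_k(meas)
  sol <- solve_constrained(meas$c_fdg_mean, meas$c_p_mean, meas$c_p_integral, kh)
  expect_equal(est$ki, sol$ki)
  expect_equal(est$vp, sol$vp)
  expect_equal(est$ki_sd, 0)
})

test_that("Monte-Carlo estimate matches a direct reimplementation on the same seed stream", {
  meas <- noiseless_meas(ki = 0.04, vp = 0.3)
  meas$c_fdg_var <- (0.05 * meas$c_fdg_mean)^2
  meas$c_p_var <- (0.03 * meas$c_p_mean)^2
  for (mode in c("per_timepoint", "shared")) {
    n <- 500
    K <- nrow(meas)
    est <- monte_carlo_estimate(meas, n_draws = n, seed = 42, sigma_p_mode = mode)
    # oracle: explicit per-draw loop over the documented stream
    set.seed(42)
    eps_fdg <- matrix(rnorm(n * K), n, K)
    eps_p <- if (mode == "shared") {
      matrix(rnorm(n) * sqrt(mean(meas$c_p_var)), n, K)
    } else {
      sweep(matrix(rnorm(n * K), n, K), 2, sqrt(meas$c_p_var), `*`)
    }
    kh <- hunter_k(meas)
    xs <- ys <- numeric(n)
    for (i in seq_len(n)) {
      cf <- pmax(meas$c_fdg_mean + eps_fdg[i, ] * sqrt(meas$c_fdg_var), 0)
      cp <- pmax(meas$c_p_mean + eps_p[i, ], 0)
      icp <- meas$c_p_integral * cp / meas$c_p_mean
      # independent per-draw solve: bounded 1D minimization over x of the
      # profiled objective (y solved in closed form and clamped)
      prof <- function(x) {
        y <- max(sum(cp * (cf - x * icp)) / sum(cp^2), 0)
        sum((x * icp + y * cp - cf)^2)
      }
      opt <- optimize(prof, c(0, kh), tol = 1e-12)
      xs[i] <- opt$minimum
      ys[i] <- max(sum(cp * (cf - xs[i] * icp)) / sum(cp^2), 0)
    }
    expect_equal(est$ki, mean(xs), tolerance = 1e-6)
    expect_equal(est$vp, mean(ys), tolerance = 1e-6)
    expect_equal(est$ki_sd, sd(xs), tolerance = 1e-4)
  }
})

test_that("every Monte-Carlo Ki sample respects the box constraints", {
  meas <- noiseless_meas(ki = 0.05, vp = 0.3)
  meas$c_fdg_var <- (0.1 * meas$c_fdg_mean)^2
  meas$c_p_var <- (0.05 * meas$c_p_mean)^2
  kh <- hunter_k(meas)
  for (seed in 1:5) {
    est <- monte_carlo_estimate(meas, n_draws = 400, seed = seed)
    expect_lte(est$ki, kh)
    expect_gte(est$ki, 0)
    expect_gte(est$vp, 0)
    expect_equal(est$k_h, kh)
  }
  # determinism: identical inputs and seed give identical estimates
  a <- monte_carlo_estimate(meas, n_draws = 400, seed = 9)
  b <- monte_carlo_estimate(meas, n_draws = 400, seed = 9)
  expect_identical(c(a$ki, a$vp, a$ki_sd, a$vp_sd), c(b$ki, b$vp, b$ki_sd, b$vp_sd))
})

test_that("lesion 3-slice statistic picks fixed per-slice maxima", {
  # craft statistics with known slice maxima 100/110/120 around the peak
  d3 <- c(8, 8, 8)
  base <- array(1, d3)
  base[4, 4, 4] <- 110
  base[5, 4, 3] <- 100
  base[4, 5, 5] <- 120
  wins <- lapply(1:5, function(w) base)
  ws <- structure(list(bins = lapply(1:5, function(b)
    list(windows = wins, window_mid_times = 80 + b)),
    bin_mid_times = 80 + (1:5), n_windows = 5L, voxel_size = c(4, 4, 4)),
    class = "window_set")
  st <- mean_variance_images(ws)
  mask <- array(FALSE, d3)
  mask[3:6, 3:6, 3:5] <- TRUE
  lss <- lesion_slice_statistics(st, mask)
  expect_equal(unname(lss$c_fdg_mean), rep(110, 5))
  expect_equal(unname(lss$c_fdg_var), rep(100, 5))
  # identical values in the 3 slices give zero variance
  base2 <- array(1, d3)
  base2[4, 4, 3:5] <- 50
  ws$bins <- lapply(ws$bins, function(b) {
    b$windows <- lapply(b$windows, function(w) base2)
    b
  })
  st2 <- mean_variance_images(ws)
  lss2 <- lesion_slice_statistics(st2, mask)
  expect_equal(unname(lss2$c_fdg_var), rep(0, 5))
  # thin lesions are rejected
  thin <- array(FALSE, d3)
  thin[, , 4] <- TRUE
  expect_error(lesion_slice_statistics(st, thin), "3 slices")
})

test_that("lesion-level estimator equals Patlak on noiseless data", {
  st <- fix_clean_stats()
  ph <- fix_phantom()
  fn <- fix_input_fn()
  t_k <- st$bin_mid_times
  # zero-variance blood samples: the Monte-Carlo collapses to the
  # deterministic constrained solution on its own measurement tuples
  bs <- blood_samples(t_k, evaluate_cp(fn, t_k), counting_cv = 0)
  lss <- lesion_slice_statistics(st, ph$lesion_mask)
  est <- barbolosi_lesion(st, ph$lesion_mask, bs, fn, n_draws = 100, seed = 1)
  scaled <- scale_to_samples(fn, bs$time_min, bs$activity_bq_ml)
  meas <- measurement_set(t_k, lss$c_fdg_mean, lss$c_fdg_var,
                          evaluate_cp(fn, t_k), rep(0, 5),
                          integrate_cp(scaled, t_k))
  pat <- patlak_fit(meas)
  expect_equal(est$ki, pat$ki, tolerance = 1e-6)
  expect_equal(est$vp, pat$vp, tolerance = 1e-4)
})

test_that("voxel-level mapping with zero-variance statistics is constrained least squares", {
  st <- fix_clean_stats()
  ph <- fix_phantom()
  fn <- fix_input_fn()
  # zero all variances (tissue and blood)
  st0 <- st
  st0$var_images <- lapply(st0$var_images, function(v) v * 0)
  idif <- idif_from_roi(st0, ph$aorta_mask)
  idif$c_p_var[] <- 0
  mask <- array(FALSE, dim(ph$lesion_mask))
  mask[16, 16, 6:8] <- TRUE  # a necrotic and two viable voxels
  map <- parapet_voxel(st0, idif, mask, fn, n_draws = 10, seed = 1)
  fn_scaled <- scale_to_samples(fn, idif$t, idif$c_p_mean)
  icp <- integrate_cp(fn_scaled, st0$bin_mid_times)
  for (v in which(mask)) {
    cf <- vapply(st0$mean_images, function(img) img[v], 0)
    kh <- cf[1] / icp[1]
    sol <- solve_constrained(cf, idif$c_p_mean, icp, kh)
    expect_equal(map$ki_map[v], sol$ki, tolerance = 1e-12)
    expect_equal(map$vp_map[v], sol$vp, tolerance = 1e-12)
  }
})

test_that("voxel-level map recovers kinetics and localizes Ki_max outside necrosis", {
  ph <- fix_phantom()
  st <- fix_noisy_stats(alpha = 75, seed = 7)
  idif <- idif_from_roi(st, ph$aorta_mask)
  map <- parapet_voxel(st, idif, ph$lesion_mask, fix_input_fn(),
                       n_draws = 300, seed = 1)
  viable <- ph$lesion_mask & !ph$necrotic_mask
  med_err <- median(abs(map$ki_map[viable] - 0.05) / 0.05)
  expect_lt(med_err, 0.10)
  cc <- map$ki_max_coord
  expect_false(ph$necrotic_mask[cc[1], cc[2], cc[3]])
  # bit-identical reproducibility under the same master seed
  map2 <- parapet_voxel(st, idif, ph$lesion_mask, fix_input_fn(),
                        n_draws = 300, seed = 1)
  expect_identical(map$ki_map, map2$ki_map)
  expect_identical(map$vp_map, map2$vp_map)
  expect_error(parapet_voxel(st, idif, array(FALSE, dim(ph$lesion_mask))), "empty")
})

test_that("SUV image is the dose-per-weight normalization", {
  vol <- array(10500, c(2, 2, 2))
  suv <- suv_image(vol, injected_dose = 262.5e6, body_weight = 75000)
  expect_equal(suv[1, 1, 1], 3.0)
  # activity equal to dose/weight gives SUV 1 everywhere
  expect_equal(suv_image(array(3500, c(2, 2)), 262.5e6, 75000),
               array(1, c(2, 2)))
  # doubling weight at fixed dose doubles SUV
  expect_equal(suv_image(vol, 262.5e6, 150000), 2 * suv)
  expect_error(suv_image(vol, 0, 75000), "positive")
})
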
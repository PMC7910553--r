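test_that("leakiness from fluxes is the scaled leak over delivery", {
  expect_equal(leakiness_from_fluxes(0.0028, 500, 500, 40), 0)
  # wildtype-like magnitudes, hand arithmetic
  expect_equal(leakiness_from_fluxes(0.0028, 4634.8, 155.8, 43.2),
               0.0028 * 4479 / 43.2, tolerance = 1e-12)
  expect_equal(round(leakiness_from_fluxes(0.0028, 155.8 + 4479, 155.8, 43.2), 3),
               0.290)
  # linear in gbs at a fixed gradient and delivery
  expect_equal(leakiness_from_fluxes(0.0056, 1000, 500, 40),
               2 * leakiness_from_fluxes(0.0028, 1000, 500, 40))
  expect_error(leakiness_from_fluxes(0.0028, 1000, 500, 0), "vp")
})

test_that("gbs initial-slope estimator is exact on a perfect line", {
  cv <- gas_exchange_curve(ci = c(0, 25, 50, 75, 100),
                           a_net = 0.0028 * c(0, 25, 50, 75, 100) - 0.2,
                           label = "DCDP-fed synthetic line")
  fit <- estimate_gbs_initial_slope(cv, ci_max = 100)
  expect_equal(fit$slope, 2.8, tolerance = 1e-9)
  expect_equal(fit$slope_se, 0, tolerance = 1e-9)
  expect_equal(fit$intercept, -0.2, tolerance = 1e-9)
  # too few points in the window
  expect_error(estimate_gbs_initial_slope(cv, ci_max = 30), "insufficient")
  # a non-inhibited label warns
  cv2 <- gas_exchange_curve(ci = c(0, 50, 100), a_net = c(0, 1, 2),
                            label = "wildtype A-Ci")
  expect_warning(estimate_gbs_initial_slope(cv2), "inhibited")
})

test_that("gbs recovery from simulated inhibited curves: wildtype within band, ordering preserved", {
  cv_wt <- simulate_dcdp_curve(c4_parameters(gbs = 0.0028),
                               noise = noise_model(a_sd = 0))
  cv_mut <- simulate_dcdp_curve(c4_parameters(gbs = 0.0074),
                                noise = noise_model(a_sd = 0))
  est_wt <- estimate_gbs_initial_slope(cv_wt)$slope
  est_mut <- estimate_gbs_initial_slope(cv_mut)$slope
  expect_lt(abs(est_wt / 2.8 - 1), 0.25)
  expect_gt(est_mut, est_wt)
  # the initial-slope method reads low because bundle-sheath Rubisco
  # partially limits the inhibited flux; record the achieved biases
  bias_wt <- est_wt / 2.8 - 1
  bias_mut <- est_mut / 7.4 - 1
  expect_lt(bias_wt, 0)
  expect_lt(bias_mut, bias_wt)  # bias grows with gbs
  cat(sprintf("\n  [gbs recovery bias: %.1f%% at 2.8, %.1f%% at 7.4]\n",
              100 * bias_wt, 100 * bias_mut))
})

test_that("gbs estimates rank-correlate with truth across the physiological range", {
  set.seed(3)
  true_gbs <- exp(runif(100, log(0.001), log(0.01)))
  est <- vapply(true_gbs, function(g) {
    cv <- simulate_dcdp_curve(c4_parameters(gbs = g),
                              noise = noise_model(a_sd = 0))
    estimate_gbs_initial_slope(cv)$slope
  }, numeric(1))
  rho <- cor(true_gbs, est, method = "spearman")
  expect_gt(rho, 0.99)
})

test_that("bundle-sheath CO2 reconstruction matches the wildtype reference and its limits", {
  # printed wildtype inputs: A = 30.2, phi = 0.29, gbs = 2.8 mmol, Ci = 0.41*380
  cbs_wt <- bundle_sheath_co2(30.2, 0.29, 2.8, 0.41 * 380, rd = 1)
  expect_equal(cbs_wt, 4635, tolerance = 0.001)
  # mutant inputs give ~1513 ubar with the same defaults
  cbs_mut <- bundle_sheath_co2(18.4, 0.34, 7.4, 0.52 * 380, rd = 1)
  expect_equal(cbs_mut, 1513, tolerance = 0.001)
  # no leak: cbs collapses to cm
  expect_equal(bundle_sheath_co2(30, 0, 2.8, 150), 150)
  # monotone: decreasing in gbs, increasing in phi
  expect_true(all(diff(bundle_sheath_co2(30.2, 0.29, c(2, 4, 6, 8), 155.8)) < 0))
  expect_true(all(diff(bundle_sheath_co2(30.2, c(0.1, 0.2, 0.3, 0.4), 2.8,
                                         155.8)) > 0))
  # finite mesophyll conductance shifts cm down
  expect_lt(bundle_sheath_co2(30.2, 0.29, 2.8, 155.8, gm = 1),
            bundle_sheath_co2(30.2, 0.29, 2.8, 155.8))
  expect_error(bundle_sheath_co2(30, 1, 2.8, 150), "phi")
})

test_that("quantum yield is the low-light OLS slope", {
  irr <- c(0, 25, 50, 75, 100, 150, 200)
  cv <- gas_exchange_curve(ci = rep(150, 7), a_net = 0.05 * irr - 1,
                           irradiance = irr, label = "light response")
  expect_equal(quantum_yield(cv)$slope, 0.05, tolerance = 1e-12)
  flat <- gas_exchange_curve(ci = rep(150, 7), a_net = rep(2, 7),
                             irradiance = irr)
  expect_equal(quantum_yield(flat)$slope, 0)
  expect_error(quantum_yield(cv, irradiance_max = 10), "insufficient")
  # model-generated light curve: OLS slope close to the instantaneous
  # finite-difference slope at 100 umol quanta
  p <- c4_parameters()
  lc <- light_curve(p, irradiance_grid = irr, cm = 155.8)
  cv_mod <- gas_exchange_curve(ci = rep(155.8, 7), a_net = lc$a_net,
                               irradiance = irr, label = "model")
  qy <- quantum_yield(cv_mod)$slope
  fd <- (assimilation(155.8, 100.5, p)$a_net -
           assimilation(155.8, 99.5, p)$a_net)
  expect_lt(abs(qy / fd - 1), 0.2)
})

test_that("group comparison: Welch t, ANOVA identity, and permutation agreement", {
  same <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  ht <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(ht$statistic, -3.674, tolerance = 1e-3)
  expect_equal(ht$p_value, 0.0213, tolerance = 1e-2)
  # with equal group sizes and variances the ANOVA F is t^2
  av <- compare_groups(c(1, 2, 3), c(4, 5, 6), method = "anova")
  expect_equal(av$statistic, ht$statistic^2, tolerance = 1e-9)
  expect_error(compare_groups(1, c(1, 2)), "n >= 2")
  # permutation cross-check on random small datasets
  set.seed(21)
  diffs <- vapply(1:20, function(i) {
    a <- rnorm(8); b <- rnorm(8, mean = runif(1, 0, 1.5))
    p_t <- compare_groups(a, b)$p_value
    obs <- abs(mean(a) - mean(b))
    pooled <- c(a, b)
    perm <- replicate(1000, {
      s <- sample(16, 8)
      abs(mean(pooled[s]) - mean(pooled[-s]))
    })
    abs(p_t - mean(perm >= obs))
  }, numeric(1))
  expect_lt(max(diffs), 0.06)
})
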
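test_that("parameter invariants are enforced", {
  expect_error(c4_parameters(gbs = -1), "gbs")
  expect_error(c4_parameters(alpha = 1.5), "alpha")
  expect_error(c4_parameters(theta = 1), "theta")
  expect_error(c4_parameters(rd = 1, rm = 2), "rm")
  p <- update_parameters(c4_parameters(), gbs = 0.0074)
  expect_equal(p$gbs, 0.0074)
  expect_error(update_parameters(c4_parameters(), nope = 1), "unknown")
})

test_that("PEP carboxylation follows the capped Michaelis-Menten rule", {
  p <- c4_parameters()
  expect_identical(pep_carboxylation_rate(0, p), 0)
  # Michaelis midpoint with the regeneration cap lifted
  p_nocap <- update_parameters(p, vpr = 1e9)
  expect_equal(pep_carboxylation_rate(p$kp, p_nocap), p$vpmax / 2)
  # cap engaged at high substrate: min rule, evaluated by hand
  p_cap <- update_parameters(p, vpr = 0.8 * p$vpmax)
  expect_equal(pep_carboxylation_rate(10 * p$kp, p_cap), 0.8 * p$vpmax)
  # monotone in cm
  vps <- pep_carboxylation_rate(seq(0, 500, by = 10), p)
  expect_true(all(diff(vps) >= 0))
  expect_error(pep_carboxylation_rate(-1, p), "cm")
})

test_that("enzyme-limited solution matches the exact zero-capacity root and the bisection oracle", {
  p0 <- c4_parameters(vcmax = 0)
  for (cm in c(0, 50, 200))
    expect_equal(enzyme_limited_assimilation(cm, p0)$a_net, -p0$rd,
                 tolerance = 1e-12)
  # spec'd example parameter set against the independent bisection solver
  p <- c4_parameters(vcmax = 21, vpmax = 167, vpr = 80, kp = 80, kc = 650,
                     ko = 450, gbs = 0.0028, rd = 1, rm = 0.5, alpha = 0,
                     gamma_star = 0.000193, om = 210)
  st <- enzyme_limited_assimilation(100, p)
  or <- oracle_enzyme(100, p, tol = 1e-12)
  expect_equal(st$a_net, or$a_net, tolerance = 1e-8)
  expect_equal(st$cbs, or$cbs, tolerance = 1e-8)
})

test_that("a leakier bundle sheath lowers both assimilation and bundle-sheath CO2", {
  p_wt <- c4_parameters(vcmax = 21, gbs = 0.0028)
  p_mut <- update_parameters(p_wt, gbs = 0.0074)
  wt <- enzyme_limited_assimilation(150, p_wt)
  mut <- enzyme_limited_assimilation(150, p_mut)
  expect_lt(mut$a_net, wt$a_net)
  expect_lt(mut$cbs, wt$cbs)
  # and the oracle agrees on both orderings
  expect_lt(oracle_enzyme(150, p_mut)$a_net, oracle_enzyme(150, p_wt)$a_net)
})

test_that("light-limited solution has the right limits and matches the oracle", {
  p <- c4_parameters()
  expect_equal(light_limited_assimilation(150, 0, p)$a_net, -p$rd,
               tolerance = 1e-9)
  # electron transport saturates at jmax
  expect_equal(electron_transport(1e9, p), p$jmax, tolerance = 1e-3)
  st <- light_limited_assimilation(150, 150, p)
  or <- oracle_light(150, 150, p, tol = 1e-12)
  expect_equal(st$a_net, or$a_net, tolerance = 1e-6)
  expect_equal(st$vp, or$vp, tolerance = 1e-9)
})

test_that("closed-form solutions agree with the bisection oracle over random physiological draws", {
  set.seed(7)
  for (i in 1:100) {
    p <- random_params()
    cm <- runif(1, 20, 400)
    st <- enzyme_limited_assimilation(cm, p)
    or <- oracle_enzyme(cm, p, tol = 1e-12)
    expect_equal(st$a_net, or$a_net, tolerance = 1e-6)
    irr <- runif(1, 20, 2000)
    stl <- light_limited_assimilation(cm, irr, p)
    orl <- oracle_light(cm, irr, p, tol = 1e-12)
    expect_equal(stl$a_net, orl$a_net, tolerance = 1e-6)
  }
})

test_that("every returned state satisfies mass balance and the root identity", {
  set.seed(11)
  for (i in 1:25) {
    p <- random_params()
    cm <- runif(1, 10, 400)
    st <- assimilation(cm, runif(1, 50, 2000), p)
    expect_lt(mass_balance_residual(st, p), 1e-9 * max(1, st$vp))
    q <- attr(st, "quadratic")
    resid <- q["a"] * st$a_net^2 + q["b"] * st$a_net + q["c"]
    expect_lt(abs(resid), 1e-8 * max(1, abs(q["c"])))
  }
})

test_that("assimilation() is the minimum of the two limitations", {
  p <- c4_parameters()
  # saturating light: enzyme-limited everywhere
  st <- assimilation(150, 1e5, p)
  expect_identical(st$limitation, "enzyme")
  expect_equal(st$a_net, enzyme_limited_assimilation(150, p)$a_net)
  # darkness: light-limited at -rd
  st0 <- assimilation(150, 0, p)
  expect_identical(st0$limitation, "light")
  expect_equal(st0$a_net, -p$rd, tolerance = 1e-9)
  # the crossover found on a grid scan matches a direct oracle scan
  irr <- seq(50, 2000, by = 25)
  lim <- vapply(irr, function(q) assimilation(150, q, p)$limitation, "")
  a_enz <- oracle_enzyme(150, p)$a_net
  lim_oracle <- vapply(irr, function(q)
    if (a_enz <= oracle_light(150, q, p)$a_net) "enzyme" else "light", "")
  expect_identical(lim, lim_oracle)
})

test_that("model curves are monotone and ordered by gbs as in the leaky mutant", {
  grid <- c(0, 50, 75, 100, 200, 300, 400, 600, 800, 1000, 1200)
  p_wt <- c4_parameters(gbs = 0.0028)
  p_mut <- c4_parameters(gbs = 0.0074)
  cv_wt <- aci_curve(p_wt, grid)
  cv_mut <- aci_curve(p_mut, grid)
  expect_true(all(diff(cv_wt$a_net) >= -1e-9))
  # the leaky curve lies below the wildtype one from 100 ubar up
  hi <- grid >= 100
  expect_true(all(cv_mut$a_net[hi] < cv_wt$a_net[hi]))
  # but the PEPC-dominated initial slopes stay close (a few percent apart,
  # ~5% at the printed low-Ci window) while the curves differ in level
  slope <- function(cv) coef(lm(a_net ~ ci_ubar,
                                data = as.data.frame(cv)[cv$ci_ubar <= 100, ]))[2]
  expect_lt(abs(slope(cv_mut) / slope(cv_wt) - 1), 0.1)
  # light curves are monotone in irradiance
  lc <- light_curve(p_wt)
  expect_true(all(diff(lc$a_net) >= -1e-9))
  # single-point grid reduces to assimilation()
  one <- aci_curve(p_wt, 150, irradiance = 1500)
  expect_equal(one$a_net, assimilation(150, 1500, p_wt)$a_net)
  expect_error(aci_curve(p_wt, numeric(0)), "empty")
  expect_error(aci_curve(p_wt, c(100, 50)), "increasing")
})

test_that("cbs is monotone in gbs and diverges as gbs -> 0 with vp in excess", {
  cbs_at <- function(g) enzyme_limited_assimilation(150, c4_parameters(gbs = g))$cbs
  gs <- c(0.001, 0.0028, 0.0074, 0.01)
  expect_true(all(diff(vapply(gs, cbs_at, 1)) < 0))
  st <- enzyme_limited_assimilation(150, c4_parameters(gbs = 1e-5))
  expect_gt(st$vp, st$a_net + 0.5)   # vp exceeds a_net + rm
  expect_gt(st$cbs, 1e4)
})

test_that("an unphysical parameter set raises a model-infeasibility error", {
  expect_error(c4leak:::solve_quadratic_smaller(1, 0, 1), "infeasibility")
  # tangency returns the double root
  expect_equal(c4leak:::solve_quadratic_smaller(1, -2, 1), 1)
})
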
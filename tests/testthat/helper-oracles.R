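# Independent brute-force solvers for the coupled mesophyll/bundle-sheath
# CO2 balance. These solve the balance directly by root bisection on the
# physical branch (cbs >= 0), without the closed-form quadratic used by the
# package, so they can serve as oracles for it.

# bundle-sheath O2 partial pressure (ubar) at a given net assimilation
oracle_obs_ubar <- function(a_net, p) {
  p$alpha * a_net / (0.047 * p$gbs) + p$om * 1000
}

# enzyme-limited: A = Vcmax (Cbs - g* Obs) / (Cbs + Kc (1 + Obs/Ko)) - Rd
oracle_enzyme <- function(cm, p, tol = 1e-10) {
  vp <- min(cm * p$vpmax / (cm + p$kp), p$vpr)
  f <- function(a) {
    cbs <- cm + (vp - a - p$rm) / p$gbs
    obs <- oracle_obs_ubar(a, p)
    kprime <- p$kc * (1 + obs / (p$ko * 1000))
    a - (p$vcmax * (cbs - p$gamma_star * obs) / (cbs + kprime) - p$rd)
  }
  hi <- vp - p$rm + p$gbs * cm   # A at cbs = 0
  lo <- -(p$rd + p$vcmax + 10)
  a <- uniroot(f, c(lo, hi), tol = tol)$root
  list(a_net = a, cbs = cm + (vp - a - p$rm) / p$gbs, vp = vp)
}

# light-limited: A = J3 (Cbs - g* Obs) / (Cbs + 7 g* Obs / 3) - Rd with
# J3 = (1 - x) Jt / 3 and Vp = x Jt / 2
oracle_light <- function(cm, irradiance, p, tol = 1e-10) {
  i2 <- irradiance * p$absorptance * (1 - p$f_spectral) / 2
  jt <- (i2 + p$jmax - sqrt((i2 + p$jmax)^2 - 4 * p$theta * i2 * p$jmax)) /
    (2 * p$theta)
  vp <- p$x_partition * jt / 2
  j3 <- (1 - p$x_partition) * jt / 3
  f <- function(a) {
    cbs <- cm + (vp - a - p$rm) / p$gbs
    obs <- oracle_obs_ubar(a, p)
    a - (j3 * (cbs - p$gamma_star * obs) /
           (cbs + 7 * p$gamma_star * obs / 3) - p$rd)
  }
  hi <- vp - p$rm + p$gbs * cm
  lo <- -(p$rd + j3 + 10)
  a <- uniroot(f, c(lo, hi), tol = tol)$root
  list(a_net = a, cbs = cm + (vp - a - p$rm) / p$gbs, vp = vp, jt = jt)
}

# random physiological parameter draw for property tests
random_params <- function() {
  rd <- runif(1, 0.5, 2)
  c4_parameters(vcmax = runif(1, 10, 40), vpmax = runif(1, 60, 200),
                vpr = runif(1, 40, 120), kp = runif(1, 40, 120),
                kc = runif(1, 400, 900), ko = runif(1, 300, 600),
                gbs = runif(1, 0.001, 0.01), rd = rd, rm = 0.5 * rd,
                alpha = runif(1, 0, 0.15), jmax = runif(1, 200, 500),
                theta = runif(1, 0.5, 0.9), x_partition = runif(1, 0.3, 0.5))
}

# mass-balance residual |vp - a_net - rm - gbs (cbs - cm)| of a state
mass_balance_residual <- function(st, params) {
  abs(st$vp - st$a_net - params$rm - params$gbs * (st$cbs - st$cm))
}
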
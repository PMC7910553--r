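# smaller root of a*x^2 + b*x + c = 0, with linear fallback when a == 0.
# A negative discriminant signals an unphysical parameter set and is an
# error rather than a silent clamp; an exactly-zero discriminant returns the
# double root.
solve_quadratic_smaller <- function(a, b, c) {
  if (a == 0) {
    if (b == 0) stop("degenerate quadratic: a = b = 0", call. = FALSE)
    return(-c / b)
  }
  disc <- b^2 - 4 * a * c
  if (disc < 0) {
    # allow pure round-off at the tangency point
    if (disc > -1e-12 * max(1, b^2)) disc <- 0
    else stop("model infeasibility: negative discriminant (b^2 - 4ac = ",
              format(disc), ")", call. = FALSE)
  }
  (-b - sqrt(disc)) / (2 * a)
}

#' Instantaneous state of the C4 flux model
#'
#' One solution of the coupled mesophyll/bundle-sheath CO2 balance:
#' net assimilation, PEP carboxylation, bundle-sheath CO2, the leak flux
#' `gbs * (cbs - cm)` and leakiness `leak / vp`.
#'
#' @param a_net Net CO2 assimilation (umol m-2 s-1).
#' @param vp PEP carboxylation rate (umol m-2 s-1).
#' @param cbs Bundle-sheath CO2 partial pressure (ubar).
#' @param cm Mesophyll CO2 partial pressure (ubar).
#' @param gbs Bundle-sheath conductance (mol m-2 s-1 bar-1).
#' @param limitation `"enzyme"` or `"light"`.
#' @return An object of class `c4_state`.
#' @export
c4_state <- function(a_net, vp, cbs, cm, gbs, limitation) {
  leak <- gbs * (cbs - cm)
  structure(list(a_net = a_net, vp = vp, cbs = cbs, cm = cm,
                 leak = leak, phi = if (vp > 0) leak / vp else NA_real_,
                 limitation = limitation),
            class = "c4_state")
}

#' @export
print.c4_state <- function(x, ...) {
  cat(sprintf(
    "<c4_state %s-limited> A = %.3f, Vp = %.3f umol m-2 s-1; Cbs = %.1f, Cm = %.1f ubar; leak = %.3f, phi = %s\n",
    x$limitation, x$a_net, x$vp, x$cbs, x$cm, x$leak,
    if (is.na(x$phi)) "NA" else sprintf("%.3f", x$phi)))
  invisible(x)
}

#' PEP carboxylation rate
#'
#' Michaelis-Menten CO2 response of PEP carboxylase capped by the
#' PEP-regeneration limit: `Vp = min(cm * vpmax / (cm + kp), vpr)`.
#'
#' @param cm Mesophyll CO2 partial pressure (ubar), non-negative.
#' @param params A [c4_parameters()] object.
#' @return PEP carboxylation rate (umol m-2 s-1).
#' @export
pep_carboxylation_rate <- function(cm, params) {
  stopifnot(inherits(params, "c4_parameters"))
  if (any(!is.finite(cm)) || any(cm < 0))
    stop("cm must be finite and >= 0", call. = FALSE)
  pmin(cm * params$vpmax / (cm + params$kp), params$vpr)
}

# shared quadratic assembly for the bundle-sheath CO2 balance.
# `capacity` is the carboxylation capacity (Vcmax, or (1-x)Jt/3 for the
# light-limited case), and `michaelis` switches Rubisco CO2/O2 kinetics
# (enzyme case) against the fixed ATP stoichiometry (light case).
bs_balance_roots <- function(vp, cm, capacity, params, light) {
  p <- params
  om_ub <- p$om * 1000           # mbar -> ubar
  ko_ub <- p$ko * 1000
  ar <- p$alpha / 0.047
  v <- vp - p$rm + p$gbs * cm
  if (light) {
    a <- 1 - 7 * p$gamma_star * ar / 3
    w <- v + (7 * p$gamma_star / 3) * p$gbs * om_ub
    b <- -(w - a * p$rd + capacity * (1 + p$gamma_star * ar))
    cc <- capacity * v - p$rd * w - capacity * p$gamma_star * p$gbs * om_ub
  } else {
    kprime <- p$kc * (1 + om_ub / ko_ub)
    a <- 1 - ar * (p$kc / ko_ub)
    b <- -((v) + (capacity - p$rd) + p$gbs * kprime +
             ar * (p$gamma_star * capacity + p$rd * p$kc / ko_ub))
    cc <- (capacity - p$rd) * v -
      (capacity * p$gbs * p$gamma_star * om_ub + p$rd * p$gbs * kprime)
  }
  a_net <- solve_quadratic_smaller(a, b, cc)
  list(a_net = a_net, coefs = c(a = a, b = b, c = cc))
}

#' Enzyme-limited net assimilation
#'
#' Solves the enzyme-limited coupled CO2 balance of the mesophyll and bundle
#' sheath: the net assimilation rate is the smaller root of a quadratic in A
#' obtained by combining PEPC supply, bundle-sheath leak, and Rubisco
#' CO2/O2 kinetics. Bundle-sheath CO2 follows from mass balance,
#' `cbs = cm + (vp - a_net - rm) / gbs`.
#'
#' @inheritParams pep_carboxylation_rate
#' @return A [c4_state()] with `limitation = "enzyme"`.
#' @export
enzyme_limited_assimilation <- function(cm, params) {
  stopifnot(inherits(params, "c4_parameters"))
  if (!is.finite(cm) || cm < 0) stop("cm must be finite and >= 0", call. = FALSE)
  if (params$gbs <= 0) stop("gbs must be > 0", call. = FALSE)
  vp <- pep_carboxylation_rate(cm, params)
  sol <- bs_balance_roots(vp, cm, params$vcmax, params, light = FALSE)
  cbs <- cm + (vp - sol$a_net - params$rm) / params$gbs
  st <- c4_state(sol$a_net, vp, cbs, cm, params$gbs, "enzyme")
  attr(st, "quadratic") <- sol$coefs
  st
}

#' Light-limited net assimilation
#'
#' Useful absorbed irradiance is `I2 = irradiance * absorptance *
#' (1 - f_spectral) / 2`; total electron transport `Jt` is the smaller root
#' of `theta Jt^2 - (I2 + jmax) Jt + I2 jmax = 0`. A fraction `x_partition`
#' of `Jt` drives the C4 cycle (`vp = x Jt / 2`), the remainder the
#' bundle-sheath C3 cycle with ATP-limited capacity `(1 - x) Jt / 3`. The
#' net assimilation rate is the smaller root of the quadratic analogous to
#' the enzyme-limited case.
#'
#' @inheritParams pep_carboxylation_rate
#' @param irradiance Incident irradiance (umol quanta m-2 s-1).
#' @return A [c4_state()] with `limitation = "light"`.
#' @export
light_limited_assimilation <- function(cm, irradiance, params) {
  stopifnot(inherits(params, "c4_parameters"))
  if (!is.finite(cm) || cm < 0) stop("cm must be finite and >= 0", call. = FALSE)
  if (!is.finite(irradiance) || irradiance < 0)
    stop("irradiance must be finite and >= 0", call. = FALSE)
  if (params$gbs <= 0) stop("gbs must be > 0", call. = FALSE)
  jt <- electron_transport(irradiance, params)
  vp <- params$x_partition * jt / 2
  capacity <- (1 - params$x_partition) * jt / 3
  sol <- bs_balance_roots(vp, cm, capacity, params, light = TRUE)
  cbs <- cm + (vp - sol$a_net - params$rm) / params$gbs
  st <- c4_state(sol$a_net, vp, cbs, cm, params$gbs, "light")
  attr(st, "quadratic") <- sol$coefs
  st
}

#' Total electron transport rate
#'
#' Non-rectangular hyperbola of irradiance: the smaller root of
#' `theta Jt^2 - (I2 + jmax) Jt + I2 jmax = 0`.
#'
#' @inheritParams light_limited_assimilation
#' @return Jt (umol electrons m-2 s-1).
#' @export
electron_transport <- function(irradiance, params) {
  i2 <- irradiance * params$absorptance * (1 - params$f_spectral) / 2
  solve_quadratic_smaller(params$theta, -(i2 + params$jmax), i2 * params$jmax)
}

#' Net assimilation as the minimum of enzyme- and light-limited rates
#'
#' Evaluates both limitations and returns the state with the smaller
#' assimilation rate, its `limitation` label set accordingly.
#'
#' @inheritParams light_limited_assimilation
#' @return A [c4_state()].
#' @export
assimilation <- function(cm, irradiance, params) {
  enz <- enzyme_limited_assimilation(cm, params)
  lgt <- light_limited_assimilation(cm, irradiance, params)
  if (enz$a_net <= lgt$a_net) enz else lgt
}

state_row <- function(st, irradiance) {
  data.frame(ci_ubar = st$cm, irradiance = irradiance, a_net = st$a_net,
             cbs = st$cbs, vp = st$vp, leak = st$leak, phi = st$phi,
             limitation = st$limitation, stringsAsFactors = FALSE)
}

check_grid <- function(grid, what) {
  if (length(grid) == 0) stop("empty ", what, " grid", call. = FALSE)
  if (any(!is.finite(grid)) || any(grid < 0))
    stop(what, " grid must be finite and non-negative", call. = FALSE)
  if (length(grid) > 1 && any(diff(grid) <= 0))
    stop(what, " grid must be strictly increasing", call. = FALSE)
  invisible(grid)
}

#' Model CO2-response and light-response curves
#'
#' `aci_curve()` evaluates [assimilation()] over a grid of mesophyll /
#' intercellular CO2 partial pressures at fixed irradiance; `light_curve()`
#' over an irradiance grid at fixed CO2. Both return a `c4_curve` data frame
#' with one model state per grid point; the generating parameters and
#' conditions are kept as attributes.
#'
#' @param params A [c4_parameters()] object.
#' @param ci_grid Strictly increasing, non-negative CO2 grid (ubar).
#' @param irradiance Irradiance for the CO2 response (umol quanta m-2 s-1).
#' @param irradiance_grid Strictly increasing, non-negative irradiance grid.
#' @param cm CO2 partial pressure for the light response (ubar).
#' @return A data frame of class `c4_curve` with columns `ci_ubar`,
#'   `irradiance`, `a_net`, `cbs`, `vp`, `leak`, `phi`, `limitation`.
#' @export
aci_curve <- function(params, ci_grid = c(0, 50, 75, 100, 200, 300, 400,
                                          600, 800, 1000, 1200),
                      irradiance = 1500) {
  check_grid(ci_grid, "ci")
  rows <- do.call(rbind, lapply(ci_grid, function(ci)
    state_row(assimilation(ci, irradiance, params), irradiance)))
  structure(rows, class = c("c4_curve", "data.frame"),
            params = params, kind = "aci",
            conditions = list(irradiance = irradiance))
}

#' @rdname aci_curve
#' @export
light_curve <- function(params, irradiance_grid = c(0, 25, 50, 75, 100, 150,
                                                    200, 300, 500, 750, 1000,
                                                    1500, 2000),
                        cm = 0.41 * 380) {
  check_grid(irradiance_grid, "irradiance")
  rows <- do.call(rbind, lapply(irradiance_grid, function(q)
    state_row(assimilation(cm, q, params), q)))
  structure(rows, class = c("c4_curve", "data.frame"),
            params = params, kind = "light", conditions = list(cm = cm))
}

#' Write a model curve as CSV
#'
#' @param curve A `c4_curve` from [aci_curve()] or [light_curve()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}
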
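#' Ordinary least-squares slope fit over a window of points
#'
#' Shared container for the initial-slope estimators (bundle-sheath
#' conductance, quantum yield): slope and intercept with standard errors,
#' point count, R-squared, and a description of the window used.
#'
#' @param x,y Numeric vectors (>= 3 points for a reported standard error).
#' @param window Free-text description of the window.
#' @return An object of class `slope_fit`.
#' @keywords internal
slope_fit <- function(x, y, window = "") {
  if (length(x) < 3) stop("insufficient data: need >= 3 points", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 slope_se = sm$coefficients[2, 2],
                 intercept = unname(stats::coef(fit)[1]),
                 intercept_se = sm$coefficients[1, 2],
                 n_points = length(x),
                 r_squared = sm$r.squared,
                 window = window),
            class = "slope_fit")
}

#' @export
print.slope_fit <- function(x, ...) {
  cat(sprintf("<slope_fit> slope %.4g +/- %.3g, intercept %.4g +/- %.3g (n = %d, R2 = %.4f)\n  window: %s\n",
              x$slope, x$slope_se, x$intercept, x$intercept_se,
              x$n_points, x$r_squared, x$window))
  invisible(x)
}

#' Serialise a fit result as a JSON record
#'
#' @param fit A `slope_fit` or a list with `phi`/`se`/`n` (from
#'   [fit_leakiness()]).
#' @param path Optional file; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
fit_to_json <- function(fit, path = NULL) {
  rec <- if (inherits(fit, "slope_fit")) {
    list(estimate = fit$slope, se = fit$slope_se, n = fit$n_points,
         window = fit$window)
  } else {
    list(estimate = fit$phi, se = fit$se, n = fit$n, window = fit$method)
  }
  js <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Leakiness from bundle-sheath fluxes
#'
#' Leakiness is the leak flux out of the bundle sheath over the rate of CO2
#' delivery: `phi = gbs * (cbs - cm) / vp`, with `gbs` in mol m-2 s-1 bar-1
#' and the CO2 gradient in ubar (so the product is in umol m-2 s-1).
#'
#' @param gbs Bundle-sheath conductance (mol m-2 s-1 bar-1).
#' @param cbs,cm Bundle-sheath and mesophyll CO2 partial pressures (ubar).
#' @param vp PEP carboxylation rate (umol m-2 s-1), > 0.
#' @return Leakiness (dimensionless).
#' @export
leakiness_from_fluxes <- function(gbs, cbs, cm, vp) {
  if (any(vp <= 0))
    stop("leakiness is undefined for vp <= 0", call. = FALSE)
  gbs * (cbs - cm) / vp
}

#' Bundle-sheath conductance from a PEPC-inhibited CO2 response
#'
#' With the C4 cycle inhibited (e.g. DCDP-fed leaves), CO2 reaches the
#' bundle sheath only by diffusion and the initial slope of the CO2 response
#' of assimilation approximates `gbs`. Fits an ordinary least squares line
#' (free intercept, since inhibition leaves residual fixation) to the points
#' with `ci <= ci_max` and converts the slope from
#' umol m-2 s-1 ubar-1 to mmol m-2 s-1 bar-1 (factor 1000).
#'
#' @param curve A [gas_exchange_curve()] from an inhibited leaf.
#' @param ci_max Upper edge of the initial-slope window (ubar).
#' @return A `slope_fit`; `slope` is the gbs estimate in
#'   mmol m-2 s-1 bar-1.
#' @export
estimate_gbs_initial_slope <- function(curve, ci_max = 100) {
  stopifnot(inherits(curve, "gas_exchange_curve"))
  lab <- attr(curve, "label")
  if (!grepl("dcdp|inhib", lab, ignore.case = TRUE))
    warning("curve label '", lab,
            "' does not look like a PEPC-inhibited measurement", call. = FALSE)
  sel <- curve$ci <= ci_max
  if (sum(sel) < 3)
    stop("insufficient data: fewer than 3 points with ci <= ", ci_max,
         call. = FALSE)
  fit <- slope_fit(curve$ci[sel], curve$a_net[sel],
                   window = sprintf("ci <= %g ubar (%d points)", ci_max,
                                    sum(sel)))
  # slope in umol m-2 s-1 ubar-1 == mol m-2 s-1 bar-1; report in mmol
  fit$slope <- fit$slope * 1000
  fit$slope_se <- fit$slope_se * 1000
  fit
}

#' Bundle-sheath CO2 partial pressure from flux balance
#'
#' Reconstructs bundle-sheath CO2 from leaf-level quantities: with
#' `rm = 0.5 * rd` and `cm = ci - a_net / gm` (`cm = ci` at infinite
#' mesophyll conductance, the default), the PEP carboxylation rate follows
#' from `vp = (a_net + rm) / (1 - phi)`, the leak from `leak = phi * vp`,
#' and `cbs = cm + 1000 * leak / gbs` with `gbs` in mmol m-2 s-1 bar-1.
#'
#' @param a_net Net CO2 assimilation (umol m-2 s-1).
#' @param phi Leakiness, in `[0, 1)`.
#' @param gbs Bundle-sheath conductance (mmol m-2 s-1 bar-1).
#' @param ci Intercellular CO2 partial pressure (ubar).
#' @param rd Leaf mitochondrial respiration (umol m-2 s-1).
#' @param gm Mesophyll conductance (mol m-2 s-1 bar-1); `Inf` for `cm = ci`.
#' @return Bundle-sheath CO2 partial pressure (ubar).
#' @export
bundle_sheath_co2 <- function(a_net, phi, gbs, ci, rd = 1.0, gm = Inf) {
  if (any(phi < 0) || any(phi >= 1))
    stop("phi must lie in [0, 1)", call. = FALSE)
  if (any(gbs <= 0)) stop("gbs must be > 0", call. = FALSE)
  rm <- 0.5 * rd
  cm <- if (is.infinite(gm)) ci else ci - a_net / gm
  vp <- (a_net + rm) / (1 - phi)
  leak <- phi * vp
  cm + 1000 * leak / gbs
}

#' Quantum yield from the initial slope of a light response
#'
#' Ordinary least squares of net assimilation on incident irradiance over
#' the low-light window (default 0-200 umol quanta m-2 s-1), giving the
#' apparent quantum yield in mol CO2 per mol incident quanta.
#'
#' @param curve A [gas_exchange_curve()] with irradiance values.
#' @param irradiance_max Upper edge of the low-light window.
#' @return A `slope_fit`; `slope` is the quantum yield.
#' @export
quantum_yield <- function(curve, irradiance_max = 200) {
  stopifnot(inherits(curve, "gas_exchange_curve"))
  sel <- !is.na(curve$irradiance) & curve$irradiance <= irradiance_max
  if (sum(sel) < 3)
    stop("insufficient data: fewer than 3 points with irradiance <= ",
         irradiance_max, call. = FALSE)
  slope_fit(curve$irradiance[sel], curve$a_net[sel],
            window = sprintf("irradiance <= %g (%d points)", irradiance_max,
                             sum(sel)))
}

#' Two-group comparison
#'
#' Welch's unequal-variance t-test by default, or a one-way ANOVA; for two
#' groups the (equal-variance) ANOVA F equals the pooled t squared.
#'
#' @param values_a,values_b Numeric vectors, each with n >= 2.
#' @param method `"t_test"` (Welch) or `"anova"`.
#' @return A list with `statistic`, `p_value`, `method`, and `df`.
#' @export
compare_groups <- function(values_a, values_b, method = c("t_test", "anova")) {
  method <- match.arg(method)
  if (length(values_a) < 2 || length(values_b) < 2)
    stop("each group needs n >= 2", call. = FALSE)
  if (method == "t_test") {
    ht <- stats::t.test(values_a, values_b, var.equal = FALSE)
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         method = "welch_t", df = unname(ht$parameter))
  } else {
    g <- factor(rep(c("a", "b"), c(length(values_a), length(values_b))))
    fit <- stats::aov(c(values_a, values_b) ~ g)
    sm <- summary(fit)[[1]]
    list(statistic = sm[["F value"]][1], p_value = sm[["Pr(>F)"]][1],
         method = "anova_f", df = sm[["Df"]])
  }
}
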
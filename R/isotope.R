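#' Constants of the simplified C4 discrimination model
#'
#' The linear relation between photosynthetic 13C discrimination and
#' leakiness, `delta = a_diff + (b4 - a_diff + phi_coeff * phi) * ci_over_ca`,
#' uses three constants: the diffusional fractionation `a_diff` (4.3 per
#' mil), the combined fractionation of CO2 dissolution, hydration and PEP
#' carboxylation `b4` (-5.7 per mil), and the coefficient on leakiness
#' `phi_coeff` (27.2 per mil), which lumps the Rubisco fractionation felt
#' through the leak. Defaults are the values used for C4 leaves at infinite
#' mesophyll conductance; all are overridable.
#'
#' @param a_diff Diffusional fractionation (per mil).
#' @param b4 Net fractionation of the C4 carboxylation path (per mil).
#' @param phi_coeff Coefficient on leakiness (per mil).
#' @return An object of class `isotope_constants`.
#' @export
isotope_constants <- function(a_diff = 4.3, b4 = -5.7, phi_coeff = 27.2) {
  stopifnot(is.finite(a_diff), is.finite(b4), is.finite(phi_coeff))
  structure(list(a_diff = a_diff, b4 = b4, phi_coeff = phi_coeff),
            class = "isotope_constants")
}

#' Forward discrimination from leakiness
#'
#' @param phi Leakiness (dimensionless).
#' @param ci_over_ca Ratio of intercellular to ambient CO2.
#' @param constants An [isotope_constants()] object.
#' @return Predicted 13C discrimination (per mil).
#' @export
discrimination_from_leakiness <- function(phi, ci_over_ca,
                                          constants = isotope_constants()) {
  k <- constants
  k$a_diff + (k$b4 - k$a_diff + k$phi_coeff * phi) * ci_over_ca
}

#' Leakiness from measured discrimination
#'
#' Exact algebraic inversion of [discrimination_from_leakiness()]:
#' `phi = ((delta - a_diff) / ci_over_ca - (b4 - a_diff)) / phi_coeff`.
#'
#' @param delta Measured 13C discrimination (per mil).
#' @inheritParams discrimination_from_leakiness
#' @return Leakiness (dimensionless).
#' @export
leakiness_from_discrimination <- function(delta, ci_over_ca,
                                          constants = isotope_constants()) {
  if (any(ci_over_ca == 0))
    stop("ci_over_ca = 0: discrimination carries no leakiness information",
         call. = FALSE)
  k <- constants
  ((delta - k$a_diff) / ci_over_ca - (k$b4 - k$a_diff)) / k$phi_coeff
}

#' Isotope-discrimination observations
#'
#' One row per combined tuneable-diode-laser / gas-exchange measurement:
#' discrimination, the concurrent Ci/Ca ratio, and ambient CO2.
#'
#' @param delta 13C discrimination (per mil).
#' @param ci_over_ca Ci/Ca ratio, in (0, 1).
#' @param ca Ambient CO2 partial pressure (ubar).
#' @return A data frame of class `isotope_observations`.
#' @export
isotope_observations <- function(delta, ci_over_ca, ca = 380) {
  if (any(!is.finite(delta))) stop("delta must be finite", call. = FALSE)
  if (any(ci_over_ca <= 0) || any(ci_over_ca >= 1))
    stop("ci_over_ca must lie in (0, 1)", call. = FALSE)
  structure(data.frame(delta = delta, ci_over_ca = ci_over_ca,
                       ca = rep_len(ca, length(delta))),
            class = c("isotope_observations", "data.frame"))
}

#' Read isotope observations from CSV
#'
#' Expects columns `delta_permil`, `ci_over_ca`, `ca_ubar`.
#'
#' @param path CSV file.
#' @return An [isotope_observations()] data frame.
#' @export
read_isotope_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("delta_permil", "ci_over_ca", "ca_ubar")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s) ", paste(miss, collapse = ", "),
                         " in ", path, call. = FALSE)
  isotope_observations(df$delta_permil, df$ci_over_ca, df$ca_ubar)
}

#' Write isotope observations to CSV
#'
#' @param obs An [isotope_observations()] data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_isotope_csv <- function(obs, path) {
  utils::write.csv(data.frame(delta_permil = obs$delta,
                              ci_over_ca = obs$ci_over_ca,
                              ca_ubar = obs$ca),
                   path, row.names = FALSE)
  invisible(path)
}

#' Estimate leakiness from a set of discrimination observations
#'
#' The default estimator inverts each observation through
#' [leakiness_from_discrimination()] and reports the mean with the standard
#' error of the mean, matching per-plant aggregation of replicate leaves.
#' The `"regression"` method instead regresses `delta - a_diff` on
#' `ci_over_ca` through the origin and maps the fitted slope to leakiness;
#' the two coincide when all observations share one Ci/Ca.
#'
#' @param observations An [isotope_observations()] data frame (>= 2 rows).
#' @param constants An [isotope_constants()] object.
#' @param method `"mean_inversion"` (default) or `"regression"`.
#' @return A list with `phi`, `se`, `n`, and `method`.
#' @export
fit_leakiness <- function(observations, constants = isotope_constants(),
                          method = c("mean_inversion", "regression")) {
  method <- match.arg(method)
  if (nrow(observations) < 2)
    stop("need at least 2 observations", call. = FALSE)
  k <- constants
  if (method == "mean_inversion") {
    phis <- leakiness_from_discrimination(observations$delta,
                                          observations$ci_over_ca, k)
    est <- mean(phis)
    se <- stats::sd(phis) / sqrt(length(phis))
  } else {
    y <- observations$delta - k$a_diff
    r <- observations$ci_over_ca
    fit <- stats::lm(y ~ 0 + r)
    slope <- stats::coef(fit)[["r"]]
    slope_se <- sqrt(stats::vcov(fit)[1, 1])
    est <- (slope - (k$b4 - k$a_diff)) / k$phi_coeff
    se <- slope_se / k$phi_coeff
  }
  list(phi = est, se = se, n = nrow(observations), method = method)
}
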
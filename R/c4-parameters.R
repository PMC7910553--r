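#' Kinetic and conductance constants of the C4 flux model
#'
#' Bundles the parameters of the coupled mesophyll/bundle-sheath flux model:
#' maximal carboxylation capacities, Michaelis constants, bundle-sheath
#' conductance, respiration terms, Rubisco specificity, and the light-reaction
#' constants used by the light-limited solution.
#'
#' Unit conventions: 1 umol mol-1 is treated as 1 ubar at 1 bar total
#' pressure. CO2 partial pressures and CO2 Michaelis constants are in ubar,
#' O2 partial pressure and the O2 Michaelis constant in mbar, rates in
#' umol m-2 s-1, and conductances in mol m-2 s-1 bar-1 internally
#' (reported as mmol m-2 s-1 bar-1 where leaf-level estimates are quoted).
#'
#' @param vcmax Maximal Rubisco carboxylation rate (umol m-2 s-1).
#' @param vpmax Maximal PEP carboxylation rate (umol m-2 s-1).
#' @param vpr PEP-regeneration cap on the C4 cycle (umol m-2 s-1).
#' @param kp PEPC Michaelis constant for CO2 (ubar).
#' @param kc Rubisco Michaelis constant for CO2 (ubar).
#' @param ko Rubisco Michaelis constant for O2 (mbar).
#' @param gbs Bundle-sheath conductance to CO2 (mol m-2 s-1 bar-1).
#' @param rd Leaf mitochondrial respiration in the light (umol m-2 s-1).
#' @param rm Mesophyll share of `rd` (umol m-2 s-1); must not exceed `rd`.
#' @param gamma_star Half the reciprocal of Rubisco CO2/O2 specificity
#'   (dimensionless, per unit O2 pressure).
#' @param alpha Fraction of O2 evolution occurring in the bundle sheath
#'   (0 for NADP-ME leaves with PSII-poor bundle sheath).
#' @param om Mesophyll O2 partial pressure (mbar); 210 is 21 percent O2.
#' @param jmax Maximal whole-chain electron transport rate (umol m-2 s-1).
#' @param theta Empirical curvature of the light response of electron
#'   transport (0 < theta < 1).
#' @param f_spectral Spectral quality loss fraction of absorbed light.
#' @param absorptance Leaf absorptance.
#' @param x_partition Fraction of total electron transport allocated to the
#'   C4 (PEP regeneration) cycle.
#'
#' @return An object of class `c4_parameters` (a named list).
#' @examples
#' p <- c4_parameters()            # wildtype-like defaults
#' m <- c4_parameters(gbs = 0.0074) # leakier bundle sheath
#' @export
c4_parameters <- function(vcmax = 20.5, vpmax = 167, vpr = 80,
                          kp = 80, kc = 650, ko = 450,
                          gbs = 0.0028, rd = 1.0, rm = 0.5 * rd,
                          gamma_star = 0.000193, alpha = 0, om = 210,
                          jmax = 400, theta = 0.7, f_spectral = 0.15,
                          absorptance = 0.85, x_partition = 0.4) {
  p <- list(vcmax = vcmax, vpmax = vpmax, vpr = vpr, kp = kp, kc = kc,
            ko = ko, gbs = gbs, rd = rd, rm = rm, gamma_star = gamma_star,
            alpha = alpha, om = om, jmax = jmax, theta = theta,
            f_spectral = f_spectral, absorptance = absorptance,
            x_partition = x_partition)
  validate_c4_parameters(p)
  structure(p, class = "c4_parameters")
}

validate_c4_parameters <- function(p) {
  nonneg <- c("vcmax", "vpmax", "vpr", "kp", "kc", "ko", "gbs", "rd", "rm",
              "gamma_star", "om", "jmax", "f_spectral")
  for (nm in nonneg) {
    if (!is.finite(p[[nm]]) || p[[nm]] < 0)
      stop("c4_parameters: '", nm, "' must be finite and >= 0", call. = FALSE)
  }
  if (p$alpha < 0 || p$alpha > 1) stop("alpha must lie in [0, 1]", call. = FALSE)
  if (p$x_partition < 0 || p$x_partition > 1)
    stop("x_partition must lie in [0, 1]", call. = FALSE)
  if (p$theta <= 0 || p$theta >= 1) stop("theta must lie in (0, 1)", call. = FALSE)
  if (p$absorptance < 0 || p$absorptance > 1)
    stop("absorptance must lie in [0, 1]", call. = FALSE)
  if (p$rm > p$rd) stop("rm must not exceed rd", call. = FALSE)
  invisible(p)
}

#' Modify a parameter set
#'
#' Returns a copy of `params` with the named fields replaced and the
#' invariants re-checked. `rm` is not rescaled when `rd` changes; set both if
#' the mesophyll share should track respiration.
#'
#' @param params A [c4_parameters()] object.
#' @param ... Named fields to replace.
#' @return A `c4_parameters` object.
#' @export
update_parameters <- function(params, ...) {
  stopifnot(inherits(params, "c4_parameters"))
  changes <- list(...)
  bad <- setdiff(names(changes), names(params))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  params[names(changes)] <- changes
  validate_c4_parameters(params)
  structure(params, class = "c4_parameters")
}

#' @export
print.c4_parameters <- function(x, ...) {
  cat("<c4_parameters>\n")
  cat(sprintf("  Vcmax %.1f, Vpmax %.1f, Vpr %.1f umol m-2 s-1\n",
              x$vcmax, x$vpmax, x$vpr))
  cat(sprintf("  Kp %.0f ubar, Kc %.0f ubar, Ko %.0f mbar, gamma* %.3g\n",
              x$kp, x$kc, x$ko, x$gamma_star))
  cat(sprintf("  gbs %.4g mol m-2 s-1 bar-1 (%.2f mmol), Rd %.2f, Rm %.2f\n",
              x$gbs, 1000 * x$gbs, x$rd, x$rm))
  cat(sprintf("  O2 %.0f mbar, alpha %.2f; Jmax %.0f, theta %.2f, x %.2f\n",
              x$om, x$alpha, x$jmax, x$theta, x$x_partition))
  invisible(x)
}

#' Write / read a parameter set as a key=value config file
#'
#' Plain-text round trip for parameter sets: one `key = value` pair per line,
#' `#` comments allowed (units are written as trailing comments).
#'
#' @param params A `c4_parameters` object.
#' @param path File path.
#' @return `write_parameters` returns `path` invisibly; `read_parameters`
#'   returns a `c4_parameters` object.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "c4_parameters"))
  units <- c(vcmax = "umol m-2 s-1", vpmax = "umol m-2 s-1",
             vpr = "umol m-2 s-1", kp = "ubar", kc = "ubar", ko = "mbar",
             gbs = "mol m-2 s-1 bar-1", rd = "umol m-2 s-1",
             rm = "umol m-2 s-1", gamma_star = "dimensionless",
             alpha = "dimensionless", om = "mbar", jmax = "umol m-2 s-1",
             theta = "dimensionless", f_spectral = "fraction",
             absorptance = "fraction", x_partition = "fraction")
  lines <- vapply(names(params), function(nm) {
    sprintf("%s = %.12g  # %s", nm, params[[nm]], units[[nm]])
  }, character(1))
  writeLines(c("# C4 flux model parameters", lines), path)
  invisible(path)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(kv) != 2)) stop("malformed parameter file: ", path)
  vals <- as.list(as.numeric(trimws(vapply(kv, `[`, "", 2))))
  names(vals) <- trimws(vapply(kv, `[`, "", 1))
  do.call(c4_parameters, vals)
}
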
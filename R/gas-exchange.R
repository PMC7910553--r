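#' Measured gas-exchange curve
#'
#' Ordered observations of net CO2 assimilation against intercellular CO2
#' and/or irradiance, as produced by LI-6800-style instruments. Values are
#' stored as given; post-treatment curves may violate `ca >= ci`.
#'
#' @param ci Intercellular CO2 partial pressure (ubar), non-negative.
#' @param a_net Net CO2 assimilation (umol m-2 s-1).
#' @param irradiance Incident irradiance (umol quanta m-2 s-1).
#' @param ca Ambient CO2 partial pressure (ubar); may be `NA`.
#' @param label Free-text label (genotype / treatment, e.g. `"DCDP-fed"`).
#' @param conditions Named list of measurement conditions (leaf temperature
#'   in degrees C, O2 percent, relative humidity percent).
#' @return A data frame of class `gas_exchange_curve`.
#' @export
gas_exchange_curve <- function(ci, a_net, irradiance = NA_real_,
                               ca = NA_real_, label = "",
                               conditions = list(leaf_temp_c = 25,
                                                 o2_percent = 21,
                                                 rh_percent = 55)) {
  n <- length(ci)
  if (n < 1) stop("a gas-exchange curve needs at least one point", call. = FALSE)
  if (length(a_net) != n) stop("ci and a_net lengths differ", call. = FALSE)
  if (any(!is.finite(ci)) || any(ci < 0))
    stop("ci must be finite and >= 0", call. = FALSE)
  df <- data.frame(ci = ci, a_net = a_net,
                   irradiance = rep_len(irradiance, n),
                   ca = rep_len(ca, n))
  structure(df, class = c("gas_exchange_curve", "data.frame"),
            label = label, conditions = conditions)
}

#' @export
print.gas_exchange_curve <- function(x, ...) {
  lab <- attr(x, "label")
  cat(sprintf("<gas_exchange_curve%s> %d points, Ci %.0f-%.0f ubar\n",
              if (nzchar(lab)) paste0(" '", lab, "'") else "",
              nrow(x), min(x$ci), max(x$ci)))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Read a gas-exchange CSV
#'
#' Expects columns for assimilation, intercellular CO2, irradiance and
#' ambient CO2 (defaults `A`, `Ci`, `Qin`, `Ca`, case-insensitive), in
#' umol m-2 s-1 / umol mol-1. Extra columns are ignored.
#'
#' @param path CSV file.
#' @param aliases Named list mapping the fields `a`, `ci`, `qin`, `ca` to
#'   acceptable column names (case-insensitive).
#' @param label Curve label; defaults to the file name.
#' @return A [gas_exchange_curve()].
#' @export
read_gas_exchange <- function(path,
                              aliases = list(a = c("A", "a_net", "Anet", "Photo"),
                                             ci = c("Ci", "ci_ubar"),
                                             qin = c("Qin", "irradiance", "PARi", "Q"),
                                             ca = c("Ca", "ca_ubar", "CO2R")),
                              label = basename(path)) {
  df <- utils::read.csv(path, check.names = FALSE)
  lookup <- function(cands, required = TRUE) {
    hit <- which(tolower(names(df)) %in% tolower(cands))
    if (!length(hit)) {
      if (required)
        stop("missing column (any of: ", paste(cands, collapse = ", "),
             ") in ", path, call. = FALSE)
      return(NULL)
    }
    df[[hit[1]]]
  }
  a <- lookup(aliases$a)
  ci <- lookup(aliases$ci)
  qin <- lookup(aliases$qin, required = FALSE)
  ca <- lookup(aliases$ca, required = FALSE)
  gas_exchange_curve(ci = ci, a_net = a,
                     irradiance = if (is.null(qin)) NA_real_ else qin,
                     ca = if (is.null(ca)) NA_real_ else ca,
                     label = label)
}

#' Write a gas-exchange curve as CSV
#'
#' @param curve A [gas_exchange_curve()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gas_exchange <- function(curve, path) {
  df <- data.frame(A = curve$a_net, Ci = curve$ci,
                   Qin = curve$irradiance, Ca = curve$ca)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
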
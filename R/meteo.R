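## Meteorological conversions. Every function here must remain analytic in its
## arguments (no branching on values except hard clamps) because the
## sensitivity module pushes complex-step perturbations through them.

#' Saturation vapour pressure of water
#'
#' Magnus-type formula (Buck/Allen coefficients), adequate to well under 1%
#' over the ecological temperature range.
#'
#' @param ta air temperature (degC).
#' @return saturation vapour pressure (Pa).
#' @export
esat_pa <- function(ta) {
  611.21 * exp(17.502 * ta / (ta + 240.97))
}

#' Convert specific humidity to vapour pressure deficit
#'
#' @param qa specific humidity (kg kg-1).
#' @param ta air temperature (degC).
#' @param p surface pressure (Pa).
#' @return vapour pressure deficit (Pa); may be negative for supersaturated
#'   input, callers clamp with the configured floor.
#' @export
q_to_vpd <- function(qa, ta, p) {
  e <- qa * p / (0.622 + 0.378 * qa)
  esat_pa(ta) - e
}

#' Convert vapour pressure deficit to specific humidity
#'
#' Inverse of [q_to_vpd()] at the same temperature and pressure.
#'
#' @param vpd vapour pressure deficit (Pa).
#' @param ta air temperature (degC).
#' @param p surface pressure (Pa).
#' @return specific humidity (kg kg-1).
#' @export
vpd_to_q <- function(vpd, ta, p) {
  e <- esat_pa(ta) - vpd
  0.622 * e / (p - 0.378 * e)
}

#' Photon flux of absorbed-able PAR from shortwave radiation
#'
#' @param swin incident shortwave radiation (W m-2).
#' @param cfg configuration from [eeo_config()].
#' @return photosynthetically active photon flux density (umol m-2 s-1).
#' @export
par_photon <- function(swin, cfg = eeo_config()) {
  swin * cfg$light$par_frac * cfg$light$photon_per_j
}

#' Construct a table of monthly daytime forcing
#'
#' Bundles and validates the seven drivers of the optimality model plus the
#' bookkeeping columns needed to integrate instantaneous assimilation to
#' monthly carbon mass.
#'
#' @param ta daytime air temperature (degC).
#' @param swin daytime incident shortwave radiation (W m-2).
#' @param p surface pressure (Pa).
#' @param qa specific humidity (kg kg-1). Give either `qa` or `vpd`.
#' @param vpd vapour pressure deficit (Pa); converted to `qa` if `qa` missing.
#' @param swc volumetric soil water content (m3 m-3).
#' @param ca atmospheric CO2 (ppm).
#' @param lai leaf area index (m2 m-2).
#' @param dayfrac fraction of the day that is daytime (0-1).
#' @param ndays days in the month.
#' @param year,month optional calendar labels.
#' @return data.frame with one row per month.
#' @export
meteo_month <- function(ta, swin, p, qa = NULL, vpd = NULL, swc, ca, lai,
                        dayfrac = 0.5, ndays = 30.44, year = NA, month = NA) {
  if (is.null(qa)) {
    if (is.null(vpd)) stop("supply either `qa` or `vpd`")
    qa <- vpd_to_q(vpd, ta, p)
  }
  out <- data.frame(year = year, month = month, ta = ta, swin = swin, p = p,
                    qa = qa, swc = swc, ca = ca, lai = lai,
                    dayfrac = dayfrac, ndays = ndays)
  validate_meteo(out)
  out
}

validate_meteo <- function(met) {
  stopifnot(is.data.frame(met))
  need <- c("ta", "swin", "p", "qa", "swc", "ca", "lai", "dayfrac", "ndays")
  miss <- setdiff(need, names(met))
  if (length(miss)) stop("forcing table lacks columns: ", paste(miss, collapse = ", "))
  ok <- stats::complete.cases(met[need])
  if (any(met$swin[ok] < 0)) stop("swin must be non-negative")
  if (any(met$swc[ok] < 0 | met$swc[ok] > 1)) stop("swc must lie in [0, 1]")
  if (any(met$lai[ok] < 0)) stop("lai must be non-negative")
  if (any(met$p[ok] <= 0)) stop("p must be positive")
  invisible(met)
}

#' Daytime seconds in a month
#'
#' @param dayfrac fraction of each day that is daytime.
#' @param ndays number of days in the month.
#' @return seconds of daytime in the month.
#' @export
daytime_seconds <- function(dayfrac, ndays) {
  dayfrac * 86400 * ndays
}
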
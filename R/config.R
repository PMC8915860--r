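#' Model configuration
#'
#' Returns the full set of physical and physiological constants used by the
#' optimality GPP model as a nested list. All constants live here so that an
#' alternative parameterization (e.g. different Rubisco kinetics) can be
#' swapped in without touching the model code.
#'
#' Sections:
#' \describe{
#'   \item{kinetics}{Michaelis-Menten constants of Rubisco for CO2 (\code{kc25},
#'     Pa) and O2 (\code{ko25}, Pa), the photorespiratory CO2 compensation
#'     point at 25 degC and standard pressure (\code{gammastar25}, Pa), their
#'     Arrhenius activation energies (J mol-1), the O2 mole fraction and the
#'     standard pressure \code{p0} (Pa). Values follow the widely used
#'     in-vivo C3 kinetics of Bernacchi and colleagues.}
#'   \item{capacity}{Peaked-Arrhenius parameters of the instantaneous
#'     temperature response of Vcmax and Jmax (activation/deactivation
#'     energies, entropy terms), and \code{jfrac_ref}, the fraction of Jmax at
#'     which the canopy operates under reference (peak leaf area) conditions;
#'     this closes the coordination problem and makes the reference
#'     Jmax/Vcmax ratio an output rather than a prescribed constant.}
#'   \item{light}{PAR fraction of shortwave radiation, energy-to-photon
#'     conversion (umol J-1), intrinsic quantum yield of electron transport
#'     \code{phi_j} (mol e- per mol photon) and the curvature \code{theta_j}
#'     of the non-rectangular hyperbola.}
#'   \item{water}{\code{d_floor}: lower clamp on vapour pressure deficit (Pa)
#'     protecting the sqrt(D) singularity of the least-cost solution.}
#'   \item{mwue}{Logistic mapping from volumetric soil water content to the
#'     marginal water-use-efficiency cost ratio: asymptotic cost ratio
#'     \code{beta0} (dimensionless, well-watered limit), steepness
#'     \code{k_swc} ((m3 m-3)-1), and the default site constant \code{zeta0}
#'     (m3 m-3), the soil-moisture midpoint of the stress response -- the
#'     calibrated, soil-texture-dependent quantity.}
#'   \item{c4}{\code{k_sat}: the low CO2 half-saturation constant (Pa) of the
#'     simplified, CO2-saturating C4 carboxylation scheme.}
#'   \item{coordination}{\code{timescale}: which environment the reference
#'     capacities acclimate to. Default \code{"decadal_peak"} (study-period
#'     average of the peak-LAI month); alternatives re-coordinate with
#'     annual or monthly CO2 and/or meteorology.}
#' }
#'
#' @param ... named overrides, e.g. \code{eeo_config(light = list(phi_j = 0.3))}.
#'   Overrides are merged recursively into the defaults.
#' @return nested list of constants.
#' @export
#' @examples
#' cfg <- eeo_config()
#' cfg$kinetics$kc25
eeo_config <- function(...) {
  cfg <- list(
    kinetics = list(
      kc25 = 39.97,          # Pa
      dha_kc = 79430,        # J mol-1
      ko25 = 27480,          # Pa
      dha_ko = 36380,
      gammastar25 = 4.332,   # Pa at p0
      dha_gammastar = 37830,
      o2_frac = 0.2095,
      p0 = 101325,
      rgas = 8.314,
      tref = 298.15
    ),
    capacity = list(
      ha_vcmax = 71513, hd_vcmax = 200000, ds_vcmax = 641.64,
      ha_jmax  = 49884, hd_jmax  = 200000, ds_jmax  = 640.95,
      jfrac_ref = 0.7
    ),
    light = list(
      par_frac = 0.45,       # PAR fraction of shortwave
      photon_per_j = 4.57,   # umol photons per J of PAR
      phi_j = 0.35,          # mol e- per mol photon
      theta_j = 0.85
    ),
    water = list(d_floor = 10),          # Pa
    mwue = list(beta0 = 146, k_swc = 25, zeta0 = 0.12),
    c4 = list(k_sat = 0.8),              # Pa
    coordination = list(
      timescale = "decadal_peak"
    ),
    carbon = list(gc_per_umol = 12.011e-6)  # gC per umol CO2
  )
  ov <- list(...)
  if (length(ov)) cfg <- .merge_cfg(cfg, ov)
  cfg
}

.merge_cfg <- function(base, ov) {
  for (nm in names(ov)) {
    if (is.list(ov[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- .merge_cfg(base[[nm]], ov[[nm]])
    } else {
      base[[nm]] <- ov[[nm]]
    }
  }
  base
}

.coord_timescales <- c("decadal_peak", "annual_ca", "annual_all",
                       "monthly_ca", "monthly_all")
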
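## Temperature kinetics of the photosynthesis model. All responses are
## analytic (exponentials and powers only) so complex-step differentiation
## propagates exactly through them.

.arrhenius <- function(tk, dha, cfg) {
  k <- cfg$kinetics
  exp(dha * (tk - k$tref) / (k$tref * k$rgas * tk))
}

# Peaked Arrhenius (entropy-limited deactivation at high temperature),
# normalized to 1 at the 25 degC reference.
.peaked_arrhenius <- function(tk, ha, hd, ds, cfg) {
  k <- cfg$kinetics
  num <- 1 + exp((k$tref * ds - hd) / (k$tref * k$rgas))
  den <- 1 + exp((tk * ds - hd) / (tk * k$rgas))
  .arrhenius(tk, ha, cfg) * num / den
}

#' Dynamic viscosity of liquid water
#'
#' Empirical correlation of Kestin, Sokolov and Wakeham (1978), accurate to
#' about 0.05% between 0 and 40 degC (extrapolated smoothly outside).
#'
#' @param ta water/air temperature (degC).
#' @return dynamic viscosity (mPa s).
#' @export
water_viscosity <- function(ta) {
  # log10(eta/eta20) as a rational polynomial in (20 - t)
  dt <- 20 - ta
  lg <- dt / (ta + 96) * (1.2378 - 1.303e-3 * dt + 3.06e-6 * dt^2 + 2.55e-8 * dt^3)
  1.002 * exp(log(10) * lg)
}

#' Relative viscosity of water
#'
#' Ratio of the viscosity of water at ambient temperature to its value at the
#' 298.15 K reference; scales the transpiration cost in the least-cost
#' optimization. Exactly 1 at 25 degC.
#'
#' @param ta air temperature (degC).
#' @return dimensionless viscosity ratio eta*.
#' @export
eta_star <- function(ta) {
  water_viscosity(ta) / water_viscosity(25)
}

#' Temperature-dependent enzyme kinetics and capacities
#'
#' Evaluates, at the given daytime temperature and pressure, the effective
#' Michaelis-Menten coefficient of Rubisco K (CO2 with O2 competition), the
#' photorespiratory compensation point gamma*, the viscosity ratio eta*, and
#' the instantaneous Vcmax/Jmax scaled from their 25 degC reference values by
#' a peaked Arrhenius response.
#'
#' @param ta daytime air temperature (degC), within [-40, 60].
#' @param p surface pressure (Pa).
#' @param vcmax25 reference maximum carboxylation rate at 25 degC
#'   (umol m-2 s-1).
#' @param jmax25 reference maximum electron transport rate at 25 degC
#'   (umol m-2 s-1).
#' @param cfg configuration from [eeo_config()].
#' @return list with elements `K`, `gamma_star` (Pa), `eta_star`
#'   (dimensionless), `vcmax`, `jmax` (umol m-2 s-1).
#' @export
#' @examples
#' kinetics_at(25, 101325, 60, 120)$eta_star  # exactly 1
kinetics_at <- function(ta, p, vcmax25 = NA_real_, jmax25 = NA_real_,
                        cfg = eeo_config()) {
  if (any(Re(ta) < -40 | Re(ta) > 60, na.rm = TRUE)) {
    stop("kinetics_at: `ta` outside [-40, 60] degC")
  }
  if (any(Re(p) <= 0, na.rm = TRUE)) stop("kinetics_at: `p` must be positive")
  k <- cfg$kinetics
  tk <- ta + 273.15
  kc <- k$kc25 * .arrhenius(tk, k$dha_kc, cfg)
  ko <- k$ko25 * .arrhenius(tk, k$dha_ko, cfg)
  o2 <- k$o2_frac * p
  K <- kc * (1 + o2 / ko)
  gs <- k$gammastar25 * (p / k$p0) * .arrhenius(tk, k$dha_gammastar, cfg)
  cp <- cfg$capacity
  list(
    K = K,
    gamma_star = gs,
    eta_star = eta_star(ta),
    vcmax = vcmax25 * .peaked_arrhenius(tk, cp$ha_vcmax, cp$hd_vcmax, cp$ds_vcmax, cfg),
    jmax = jmax25 * .peaked_arrhenius(tk, cp$ha_jmax, cp$hd_jmax, cp$ds_jmax, cfg)
  )
}
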
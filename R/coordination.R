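## Photosynthetic coordination: reference capacities acclimate so that the
## Rubisco- and electron-transport-limited rates are co-limiting under the
## average daytime environment of the peak leaf-area month. The operating
## point of electron transport at reference conditions (J = jfrac_ref * Jmax)
## closes the two-unknown problem, so the reference Jmax/Vcmax ratio emerges
## from the site climate instead of being prescribed.

#' Solve reference photosynthetic capacities by coordination
#'
#' Given the reference-month environment and canopy-absorbed photon flux,
#' returns the 25 degC reference Vcmax and Jmax (canopy scale) such that the
#' Rubisco-limited and RuBP-regeneration-limited assimilation rates are
#' exactly equal at reference conditions, with electron transport running at
#' the configured fraction of Jmax.
#'
#' @param ref_met single-row forcing (list or data.frame row) with `ta`,
#'   `swc`, `qa`, `p`, `ca` of the reference (peak leaf-area) month.
#' @param iabs_ref canopy-absorbed photon flux at reference conditions
#'   (umol m-2 s-1), must be positive.
#' @param zeta0 site water-cost constant, see [mwue_beta()].
#' @param pathway "C3" or "C4".
#' @param cfg configuration from [eeo_config()].
#' @return list with `vcmax25`, `jmax25` (umol m-2 s-1, canopy scale at
#'   reference absorption), `jv_ratio` (= jmax25 / vcmax25) and `ci_ref` (Pa).
#' @export
coordinate_capacity <- function(ref_met, iabs_ref, zeta0, pathway = "C3",
                                cfg = eeo_config()) {
  if (!is.finite(iabs_ref) || iabs_ref <= 0) {
    stop("coordinate_capacity: reference absorbed light must be positive (month ",
         if (!is.null(ref_met$month)) ref_met$month else "?", ")")
  }
  kin <- kinetics_at(ref_met$ta, ref_met$p, cfg = cfg)
  kin_chi <- .chi_kinetics(kin, pathway, cfg)
  d <- q_to_vpd(ref_met$qa, ref_met$ta, ref_met$p)
  beta <- mwue_beta(ref_met$swc, zeta0, cfg)
  ca_pp <- ref_met$ca * 1e-6 * ref_met$p
  ci <- optimal_chi(ca_pp, d, kin_chi, beta, cfg)$ci

  f <- cfg$capacity$jfrac_ref
  th <- cfg$light$theta_j
  phi_i <- cfg$light$phi_j * iabs_ref
  jmax_inst <- phi_i * (1 - f) / (f * (1 - th * f))
  j_op <- f * jmax_inst
  if (pathway == "C4") {
    vcmax_inst <- j_op / 4
  } else {
    vcmax_inst <- (j_op / 4) * (ci + kin$K) / (ci + 2 * kin$gamma_star)
  }

  tk <- ref_met$ta + 273.15
  cp <- cfg$capacity
  fv <- .peaked_arrhenius(tk, cp$ha_vcmax, cp$hd_vcmax, cp$ds_vcmax, cfg)
  fj <- .peaked_arrhenius(tk, cp$ha_jmax, cp$hd_jmax, cp$ds_jmax, cfg)
  vcmax25 <- vcmax_inst / fv
  jmax25 <- jmax_inst / fj
  list(vcmax25 = vcmax25, jmax25 = jmax25,
       jv_ratio = jmax25 / vcmax25, ci_ref = ci)
}

# kinetics as seen by the least-cost chi criterion: the C4 pump removes the
# photorespiratory compensation point and replaces K by the low saturation
# constant of the simplified C4 carboxylation scheme
.chi_kinetics <- function(kin, pathway, cfg) {
  if (pathway == "C4") {
    list(K = cfg$c4$k_sat + 0 * kin$K, gamma_star = 0 * kin$gamma_star,
         eta_star = kin$eta_star)
  } else {
    kin
  }
}
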
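## FvCB assimilation: A = min(Ac, Aj). The Rubisco-limited (light-saturated)
## branch responds strongly to CO2; the RuBP-regeneration (light-limited)
## branch is capped by electron transport.

#' Electron transport rate
#'
#' Non-rectangular hyperbola in absorbed photon flux with curvature theta and
#' intrinsic quantum yield phi, saturating at Jmax.
#'
#' @param iabs absorbed photon flux (umol photons m-2 s-1).
#' @param jmax maximum electron transport rate (umol m-2 s-1).
#' @param cfg configuration from [eeo_config()].
#' @return electron transport rate J (umol e- m-2 s-1).
#' @export
electron_transport <- function(iabs, jmax, cfg = eeo_config()) {
  phi_i <- cfg$light$phi_j * iabs
  th <- cfg$light$theta_j
  b <- phi_i + jmax
  (b - sqrt(b^2 - 4 * th * phi_i * jmax)) / (2 * th)
}

#' C3 assimilation (FvCB)
#'
#' A = min(Ac, Aj) with Ac = Vcmax (ci - gamma*) / (ci + K) and
#' Aj = (J/4) (ci - gamma*) / (ci + 2 gamma*). `ci < gamma*` yields A <= 0
#' (flagged, not an error).
#'
#' @param ci intercellular CO2 partial pressure (Pa).
#' @param iabs absorbed photon flux (umol m-2 s-1).
#' @param kin kinetics list from [kinetics_at()] with instantaneous `vcmax`
#'   and `jmax`.
#' @param cfg configuration from [eeo_config()].
#' @return list with `a` (umol m-2 s-1), `ac`, `aj` and `limitation`
#'   (character, "rubisco_limited" when the Rubisco branch attains the
#'   minimum, i.e. light-saturated; else "rubp_limited").
#' @export
assimilate_c3 <- function(ci, iabs, kin, cfg = eeo_config()) {
  gs <- kin$gamma_star
  ac <- kin$vcmax * (ci - gs) / (ci + kin$K)
  j <- electron_transport(iabs, kin$jmax, cfg)
  aj <- (j / 4) * (ci - gs) / (ci + 2 * gs)
  a <- .cmin(ac, aj)
  list(a = a, ac = ac, aj = aj,
       limitation = ifelse(Re(ac) <= Re(aj), "rubisco_limited", "rubp_limited"))
}

#' Simplified C4 assimilation
#'
#' Single-enzyme approximation of the C4 CO2-concentrating pathway:
#' carboxylation is effectively CO2-saturated above a low half-saturation
#' constant (`cfg$c4$k_sat`), no photorespiratory compensation point, light
#' response retained. Guarantees a positive but much weaker CO2 sensitivity
#' than the matched C3 leaf. Experimental.
#'
#' @inheritParams assimilate_c3
#' @return as [assimilate_c3()].
#' @export
assimilate_c4 <- function(ci, iabs, kin, cfg = eeo_config()) {
  sat <- ci / (ci + cfg$c4$k_sat)
  ac <- kin$vcmax * sat
  j <- electron_transport(iabs, kin$jmax, cfg)
  aj <- (j / 4) * sat
  a <- .cmin(ac, aj)
  list(a = a, ac = ac, aj = aj,
       limitation = ifelse(Re(ac) <= Re(aj), "rubisco_limited", "rubp_limited"))
}
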
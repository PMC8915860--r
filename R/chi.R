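## Least-cost stomatal optimization: the optimal ratio chi = ci/ca minimizes
## the summed unit cost of transpiration (1.6 eta* D per unit CO2 gradient)
## and carboxylation capacity maintenance (beta_cost weighted), which yields
## the closed form chi = gamma*/ca + (1 - gamma*/ca) * xi / (xi + sqrt(D))
## with xi = sqrt(beta_cost (K + gamma*) / (1.6 eta*)).

# complex-safe elementwise minimum keyed on real parts
.cmin <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  sel <- Re(a) <= Re(b)
  out <- b
  out[sel] <- a[sel]
  out
}

# complex-safe lower clamp: values below `lo` are replaced by the constant,
# killing their derivative (consistent across differentiation modes)
.cclamp_lo <- function(x, lo) {
  x[Re(x) < lo] <- lo
  x
}

#' Soil-moisture dependence of the water-carbon cost ratio
#'
#' Logistic (sigmoid) mapping from volumetric soil water content to the
#' marginal water-use-efficiency related cost ratio that weights the
#' carboxylation cost in the least-cost criterion. Drying soil lowers the
#' ratio (water becomes relatively more expensive), which closes stomata and
#' lowers ci; wet soil saturates at the universal well-watered ratio
#' `cfg$mwue$beta0`. The calibrated site constant zeta0 is the soil-moisture
#' midpoint of the stress response (m3 m-3), reflecting soil texture and
#' rooting depth, which is where the series of a seasonally drying site
#' carries information about it.
#'
#' @param swc volumetric soil water content (m3 m-3), in [0, 1].
#' @param zeta0 site-specific stress midpoint (m3 m-3, > 0).
#' @param cfg configuration from [eeo_config()]; uses `mwue$beta0` and
#'   `mwue$k_swc`.
#' @return cost ratio beta_cost (dimensionless), monotone non-decreasing in
#'   `swc`.
#' @export
mwue_beta <- function(swc, zeta0 = eeo_config()$mwue$zeta0, cfg = eeo_config()) {
  if (any(Re(zeta0) <= 0)) stop("mwue_beta: `zeta0` must be positive")
  if (any(Re(swc) < 0 | Re(swc) > 1, na.rm = TRUE)) {
    stop("mwue_beta: `swc` outside [0, 1]")
  }
  m <- cfg$mwue
  m$beta0 / (1 + exp(-m$k_swc * (swc - zeta0)))
}

#' Optimal ci/ca ratio under the least-cost criterion
#'
#' Closed-form solution for the intercellular-to-atmospheric CO2 ratio that
#' minimizes the summed unit cost of transpiration and carboxylation. chi is
#' strictly decreasing in vapour pressure deficit and increasing in the cost
#' ratio; ci = chi * ca (partial pressures).
#'
#' @param ca_pp atmospheric CO2 partial pressure (Pa).
#' @param d vapour pressure deficit (Pa); clamped below at the configured
#'   floor before sqrt.
#' @param kin kinetics list from [kinetics_at()] (uses `K`, `gamma_star`,
#'   `eta_star`).
#' @param beta_cost cost ratio from [mwue_beta()] (> 0).
#' @param cfg configuration from [eeo_config()].
#' @return list with `chi` (dimensionless), `ci` (Pa), `xi` (Pa^0.5) and
#'   `mwue`, the marginal water-use efficiency ca_pp (1 - chi) / (1.6 D) in
#'   umol CO2 per mol H2O.
#' @export
optimal_chi <- function(ca_pp, d, kin, beta_cost, cfg = eeo_config()) {
  if (any(Re(beta_cost) <= 0)) stop("optimal_chi: `beta_cost` must be positive")
  d <- .cclamp_lo(d, cfg$water$d_floor)
  if (any(Re(d) <= 0)) stop("optimal_chi: vapour pressure deficit must be positive after flooring")
  g <- kin$gamma_star / ca_pp
  xi <- sqrt(beta_cost * (kin$K + kin$gamma_star) / (1.6 * kin$eta_star))
  chi <- g + (1 - g) * xi / (xi + sqrt(d))
  ci <- chi * ca_pp
  list(chi = chi, ci = ci, xi = xi,
       mwue = ca_pp * (1 - chi) / (1.6 * d) * 1e6)
}

#' Stomatal conductance from Fick's law
#'
#' Inverts A = g (ca - ci) for the stomatal conductance to CO2.
#'
#' @param a net assimilation (umol m-2 s-1).
#' @param ca_pp atmospheric CO2 partial pressure (Pa).
#' @param ci intercellular CO2 partial pressure (Pa), must be < `ca_pp`.
#' @return conductance g in umol m-2 s-1 Pa-1 (per unit CO2 partial-pressure
#'   gradient).
#' @export
stomatal_g <- function(a, ca_pp, ci) {
  if (any(Re(ca_pp) <= Re(ci))) {
    stop("stomatal_g: degenerate gradient, ca_pp must exceed ci")
  }
  a / (ca_pp - ci)
}
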
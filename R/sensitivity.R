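## Sensitivities of GPP to the seven drivers. "analytic" mode differentiates
## the closed-form model chain exactly by algorithmic (complex-step)
## differentiation: for an analytic function, Im f(x + ih)/h equals f'(x) to
## machine precision (error O(h^2) with no subtractive cancellation, h =
## 1e-20 scaled). Coordination is frozen during differentiation: capacities
## respond to temperature only through their instantaneous response,
## mirroring the decadal-acclimation assumption.

.CSTEP_H <- 1e-20

.cstep <- function(f, x) {
  h <- .CSTEP_H * pmax(1, abs(x))
  Im(f(complex(real = x, imaginary = h))) / h
}

.driver_names <- c("ca", "lai", "ta", "swc", "qa", "swin", "p")

# central finite-difference steps per driver, balancing truncation against
# round-off; the temperature, humidity and radiation steps are small because
# the saturation-vapour-pressure curvature otherwise dominates the
# second-order truncation term
.fd_steps <- c(ca = 0.5, lai = 1e-3, ta = 0.002, swc = 1e-4, qa = 2e-6,
               swin = 0.1, p = 10)

# evaluate the model chain with one driver replaced
.gpp_with <- function(met, caps, site, cfg, driver = NULL, value = NULL) {
  v <- lapply(met[c("ca", "ta", "swc", "qa", "swin", "p", "lai")], identity)
  if (!is.null(driver)) v[[driver]] <- value
  .gpp_core(v$ca, v$ta, v$swc, v$qa, v$swin, v$p, v$lai,
            site$extinction[met$month], met$dayfrac, met$ndays,
            caps$vcmax25, caps$jmax25, caps$f_ref,
            site$zeta0, site$pathway, cfg)
}

#' Partial derivatives of GPP to the seven drivers
#'
#' Differentiates monthly GPP with respect to each driver and sums over the
#' rows of `met`, so that a table of 12 climatological months yields
#' sensitivities in gC m-2 yr-1 per driver unit (per ppm CO2 for `d_ca`,
#' i.e. beta_CO2; per K for `d_ta`; and so on).
#'
#' Analytic mode is exact algorithmic differentiation of the closed-form
#' chain (including chi's dependence on CO2, vapour pressure deficit and
#' soil water, and the instantaneous temperature response of the
#' capacities, but not re-coordination). Finite-difference mode is the
#' independent central-difference oracle; when a perturbation crosses the
#' Rubisco/RuBP co-limitation point the step is halved until both
#' evaluations sit on the same branch.
#'
#' @param met monthly forcing table (rows are summed).
#' @param site coordinated [site_model()].
#' @param mode "analytic" or "finite_difference".
#' @param cfg configuration from [eeo_config()].
#' @return named numeric vector `d_ca`, `d_lai`, `d_ta`, `d_swc`, `d_qa`,
#'   `d_swin`, `d_p`.
#' @export
partials <- function(met, site, mode = c("analytic", "finite_difference"),
                     cfg = eeo_config()) {
  mode <- match.arg(mode)
  validate_meteo(met)
  caps <- .site_capacities(met, site, cfg)
  out <- stats::setNames(numeric(7), paste0("d_", .driver_names))
  for (d in .driver_names) {
    x <- met[[d]]
    if (mode == "analytic") {
      g <- sum(.cstep(function(z) .gpp_with(met, caps, site, cfg, d, z)$gpp,
                      x))
    } else {
      h <- rep(.fd_steps[[d]], nrow(met))
      for (k in 1:40) {
        up <- .gpp_with(met, caps, site, cfg, d, x + h)
        dn <- .gpp_with(met, caps, site, cfg, d, x - h)
        cross <- up$limitation != dn$limitation
        if (!any(cross)) break
        h[cross] <- h[cross] / 2
      }
      g <- sum((up$gpp - dn$gpp) / (2 * h))
    }
    if (!is.finite(g)) stop("partials: non-finite derivative for driver ", d)
    out[paste0("d_", d)] <- g
  }
  out
}

#' Temperature-pathway decomposition of dGPP/dTa
#'
#' Splits the total temperature sensitivity into the five chain-rule
#' pathways: vapour pressure deficit (at fixed specific humidity),
#' photosynthetic capacity (Vcmax, or Jmax when light limited), the
#' Michaelis-Menten coefficient K, the CO2 compensation point gamma*, and
#' the water viscosity ratio eta*. The five terms sum to the total
#' temperature partial exactly (same differentiation machinery on both
#' sides).
#'
#' @inheritParams partials
#' @return named numeric vector `via_D`, `via_capacity`, `via_K`,
#'   `via_gamma_star`, `via_eta_star`, `total` (rows of `met` summed).
#' @export
ta_pathways <- function(met, site, cfg = eeo_config()) {
  validate_meteo(met)
  caps <- .site_capacities(met, site, cfg)
  n <- nrow(met)
  out <- c(via_D = 0, via_capacity = 0, via_K = 0, via_gamma_star = 0,
           via_eta_star = 0, total = 0)
  cp <- cfg$capacity
  for (i in seq_len(n)) {
    m <- met[i, ]
    kin <- kinetics_at(m$ta, m$p, site$vcmax25_ref, site$jmax25_ref, cfg)
    fm <- 1 - exp(-site$extinction[m$month] * m$lai)
    iabs <- par_photon(m$swin, cfg) * fm
    scale <- fm / caps$f_ref[i]
    beta <- mwue_beta(m$swc, site$zeta0, cfg)
    daysec <- daytime_seconds(m$dayfrac, m$ndays)
    ca_pp <- m$ca * 1e-6 * m$p
    d0 <- q_to_vpd(m$qa, m$ta, m$p)
    base <- list(d = d0, K = kin$K, gs = kin$gamma_star, eta = kin$eta_star,
                 vc = caps$vcmax25[i] * scale *
                   .peaked_arrhenius(m$ta + 273.15, cp$ha_vcmax, cp$hd_vcmax, cp$ds_vcmax, cfg),
                 jm = caps$jmax25[i] * scale *
                   .peaked_arrhenius(m$ta + 273.15, cp$ha_jmax, cp$hd_jmax, cp$ds_jmax, cfg))
    gpp_of <- function(repl) {
      b <- utils::modifyList(base, repl)
      .gpp_parts(ca_pp, b$d, b$K, b$gs, b$eta, b$vc, b$jm,
                 iabs, beta, daysec, site$pathway, cfg)$gpp
    }
    # dGPP/d(intermediate)
    dg <- vapply(c("d", "K", "gs", "eta", "vc", "jm"), function(nm) {
      .cstep(function(z) gpp_of(stats::setNames(list(z), nm)), base[[nm]])
    }, numeric(1))
    # d(intermediate)/dTa at fixed qa, p
    tk_of <- function(ta) ta + 273.15
    dd_dta <- .cstep(function(ta) esat_pa(ta), m$ta)
    kin_t <- function(ta, what) {
      k <- kinetics_at(ta, m$p, cfg = cfg)
      k[[what]]
    }
    dK_dta <- .cstep(function(ta) kin_t(ta, "K"), m$ta)
    dgs_dta <- .cstep(function(ta) kin_t(ta, "gamma_star"), m$ta)
    deta_dta <- .cstep(function(ta) eta_star(ta), m$ta)
    dvc_dta <- caps$vcmax25[i] * scale *
      .cstep(function(ta) .peaked_arrhenius(tk_of(ta), cp$ha_vcmax, cp$hd_vcmax, cp$ds_vcmax, cfg), m$ta)
    djm_dta <- caps$jmax25[i] * scale *
      .cstep(function(ta) .peaked_arrhenius(tk_of(ta), cp$ha_jmax, cp$hd_jmax, cp$ds_jmax, cfg), m$ta)
    via <- c(via_D = dg[["d"]] * dd_dta,
             via_capacity = dg[["vc"]] * dvc_dta + dg[["jm"]] * djm_dta,
             via_K = dg[["K"]] * dK_dta,
             via_gamma_star = dg[["gs"]] * dgs_dta,
             via_eta_star = dg[["eta"]] * deta_dta)
    out[names(via)] <- out[names(via)] + via
    out["total"] <- out["total"] + sum(via)
  }
  out
}

#' Composite (first-order) change in GPP from driver changes
#'
#' Linear combination of the sensitivity vector with per-driver changes
#' (interannual variations or long-term trends); also returns the CO2 term
#' separately as the direct CO2-fertilization effect.
#'
#' @param sens named sensitivity vector from [partials()].
#' @param deltas named numeric: changes per driver, names among `ca`, `lai`,
#'   `ta`, `swc`, `qa`, `swin`, `p`; missing names count as zero.
#' @return list with `total` and `direct_cfe` (the `d_ca * delta_ca` term).
#' @export
composite_change <- function(sens, deltas) {
  total <- 0
  for (d in .driver_names) {
    if (!is.null(deltas[[d]]) && !is.na(deltas[[d]])) {
      total <- total + sens[[paste0("d_", d)]] * deltas[[d]]
    }
  }
  dca <- if (is.null(deltas[["ca"]])) 0 else sens[["d_ca"]] * deltas[["ca"]]
  list(total = total, direct_cfe = dca)
}

#' Logarithmic GPP response ratio to CO2
#'
#' `ln(GPP_e / GPP_s) / ln(ca_e / ca_s)`: unity indicates direct
#' proportionality of GPP to CO2. The caller decides whether the inputs come
#' from all-drivers-varying runs (apparent response) or CO2-only runs
#' (direct response).
#'
#' @param gpp_s,gpp_e GPP in the starting and ending state (> 0).
#' @param ca_s,ca_e CO2 in the starting and ending state (> 0, different).
#' @return dimensionless beta^ln.
#' @export
beta_ln <- function(gpp_s, gpp_e, ca_s, ca_e) {
  if (any(c(gpp_s, gpp_e, ca_s, ca_e) <= 0)) {
    stop("beta_ln: all inputs must be positive")
  }
  if (ca_e == ca_s) stop("beta_ln: ca_e must differ from ca_s")
  log(gpp_e / gpp_s) / log(ca_e / ca_s)
}
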
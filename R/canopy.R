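## Canopy upscaling: a single big leaf whose absorbed light and capacities
## both scale with the Beer-Lambert absorbed fraction f = 1 - exp(-k LAI),
## where k is the calibrated monthly light-extinction factor (canopy shape x
## solar zenith angle climatology). Assimilation is therefore homogeneous of
## degree one in f, and the monthly extinction climatology acts on GPP
## magnitude without touching the optimality solution (chi, ci).

#' Canopy-absorbed photon flux
#'
#' Beer-Lambert absorption of the photosynthetically active fraction of
#' shortwave radiation: `par_photon(swin) * (1 - exp(-extinction * lai))`.
#' Saturating in LAI.
#'
#' @param swin incident shortwave radiation (W m-2).
#' @param lai leaf area index (m2 m-2).
#' @param extinction_m monthly light-extinction factor (> 0, dimensionless).
#' @param cfg configuration from [eeo_config()].
#' @return absorbed photon flux (umol m-2 s-1).
#' @export
absorbed_light <- function(swin, lai, extinction_m, cfg = eeo_config()) {
  par_photon(swin, cfg) * (1 - exp(-extinction_m * lai))
}

#' Construct a site model
#'
#' Container for the calibrated per-site (or per-grid-cell) constants of the
#' canopy model.
#'
#' @param extinction numeric vector of 12 monthly light-extinction factors
#'   (kept constant across years).
#' @param zeta0 water-cost site constant, see [mwue_beta()].
#' @param pathway "C3" or "C4".
#' @param vcmax25_ref,jmax25_ref reference capacities at 25 degC (canopy
#'   scale at reference absorption); usually filled by [coordinate_site()].
#' @param peak_month calendar month of maximum climatological LAI.
#' @param ref list of reference-month conditions (`ta`, `swc`, `qa`, `swin`,
#'   `p`, `ca`, `lai`, `f_ref`, `iabs_ref`).
#' @return object of class `eeo_site`.
#' @export
site_model <- function(extinction, zeta0, pathway = c("C3", "C4"),
                       vcmax25_ref = NA_real_, jmax25_ref = NA_real_,
                       peak_month = NA_integer_, ref = NULL) {
  pathway <- match.arg(pathway)
  stopifnot(length(extinction) == 12, all(extinction > 0), zeta0 > 0)
  structure(list(extinction = as.numeric(extinction), zeta0 = zeta0,
                 pathway = pathway, vcmax25_ref = vcmax25_ref,
                 jmax25_ref = jmax25_ref, peak_month = peak_month, ref = ref),
            class = "eeo_site")
}

#' @export
print.eeo_site <- function(x, ...) {
  cat("<eeo_site> pathway:", x$pathway,
      " zeta0:", signif(x$zeta0, 4),
      " peak month:", x$peak_month, "\n")
  cat("  extinction:", paste(signif(x$extinction, 3), collapse = " "), "\n")
  cat("  vcmax25_ref:", signif(x$vcmax25_ref, 4),
      " jmax25_ref:", signif(x$jmax25_ref, 4), "\n")
  invisible(x)
}

# climatological reference (peak leaf-area month) conditions from a forcing
# table; ca averaged over the same month so the capacities acclimate to the
# study-period CO2
.ref_conditions <- function(met, peak_month = NULL) {
  clim <- stats::aggregate(met[c("ta", "swc", "qa", "swin", "p", "ca", "lai",
                                 "dayfrac")],
                           by = list(month = met$month), FUN = mean, na.rm = TRUE)
  if (is.null(peak_month)) peak_month <- clim$month[which.max(clim$lai)]
  ref <- as.list(clim[clim$month == peak_month, , drop = FALSE])
  ref$month <- peak_month
  ref
}

#' Coordinate the reference capacities of a site
#'
#' Builds the reference (decadal peak-LAI-month) conditions from the forcing
#' table and solves the coordination problem for the site's reference
#' capacities. Returns the site with `vcmax25_ref`, `jmax25_ref`,
#' `peak_month` and `ref` filled in.
#'
#' @param site an [site_model()] with extinction and zeta0 set.
#' @param met monthly forcing table (see [meteo_month()]) with `year` and
#'   `month` columns.
#' @param cfg configuration from [eeo_config()].
#' @return the updated `eeo_site`.
#' @export
coordinate_site <- function(site, met, cfg = eeo_config()) {
  validate_meteo(met)
  ref <- .ref_conditions(met)
  f_ref <- 1 - exp(-site$extinction[ref$month] * ref$lai)
  iabs_ref <- par_photon(ref$swin, cfg) * f_ref
  cap <- coordinate_capacity(ref, iabs_ref, site$zeta0, site$pathway, cfg)
  site$vcmax25_ref <- cap$vcmax25
  site$jmax25_ref <- cap$jmax25
  site$peak_month <- ref$month
  site$ref <- c(ref, list(f_ref = f_ref, iabs_ref = iabs_ref))
  site
}

## ---- internal engine -------------------------------------------------------
## Split in two stages so the temperature-pathway decomposition can perturb
## the post-kinetics intermediates (D, K, gamma*, eta*, Vcmax, Jmax) directly.
## All code below is complex-safe.

.gpp_parts <- function(ca_pp, d, K, gamma_star, eta_star, vcmax, jmax,
                       iabs, beta_cost, daysec, pathway, cfg) {
  kin <- list(K = K, gamma_star = gamma_star, eta_star = eta_star,
              vcmax = vcmax, jmax = jmax)
  opt <- optimal_chi(ca_pp, d, .chi_kinetics(kin, pathway, cfg), beta_cost, cfg)
  asm <- if (pathway == "C4") assimilate_c4(opt$ci, iabs, kin, cfg)
         else assimilate_c3(opt$ci, iabs, kin, cfg)
  gpp <- asm$a * daysec * cfg$carbon$gc_per_umol
  list(gpp = gpp, a = asm$a, ac = asm$ac, aj = asm$aj,
       limitation = asm$limitation, chi = opt$chi, ci = opt$ci,
       mwue = opt$mwue, ca_pp = ca_pp)
}

# full chain from the seven drivers; `ext` is the extinction factor of each
# row's calendar month, `f_ref` the absorbed fraction at reference conditions
.gpp_core <- function(ca, ta, swc, qa, swin, p, lai, ext, dayfrac, ndays,
                      vcmax25, jmax25, f_ref, zeta0, pathway, cfg) {
  ca_pp <- ca * 1e-6 * p
  d <- q_to_vpd(qa, ta, p)
  kin <- kinetics_at(ta, p, vcmax25, jmax25, cfg)
  fm <- 1 - exp(-ext * lai)
  iabs <- par_photon(swin, cfg) * fm
  scale <- fm / f_ref
  beta <- mwue_beta(swc, zeta0, cfg)
  daysec <- daytime_seconds(dayfrac, ndays)
  out <- .gpp_parts(ca_pp, d, kin$K, kin$gamma_star, kin$eta_star,
                    kin$vcmax * scale, kin$jmax * scale,
                    iabs, beta, daysec, pathway, cfg)
  out$iabs <- iabs
  out$beta_cost <- beta
  out$d <- d
  out
}

# per-row reference capacities and absorbed fractions for the configured
# coordination timescale
.site_capacities <- function(met, site, cfg) {
  ts <- cfg$coordination$timescale
  if (!ts %in% .coord_timescales) stop("unknown coordination timescale: ", ts)
  n <- nrow(met)
  if (ts == "decadal_peak") {
    return(data.frame(vcmax25 = rep(site$vcmax25_ref, n),
                      jmax25 = rep(site$jmax25_ref, n),
                      f_ref = rep(site$ref$f_ref, n)))
  }
  base_ref <- site$ref
  out <- data.frame(vcmax25 = numeric(n), jmax25 = numeric(n), f_ref = numeric(n))
  solve_one <- function(ref, f_ref) {
    iabs_ref <- par_photon(ref$swin, cfg) * f_ref
    cap <- coordinate_capacity(ref, iabs_ref, site$zeta0, site$pathway, cfg)
    c(cap$vcmax25, cap$jmax25)
  }
  if (ts %in% c("annual_ca", "annual_all")) {
    for (yy in unique(met$year)) {
      idx <- which(met$year == yy)
      ref <- base_ref
      if (ts == "annual_all") {
        pk <- idx[met$month[idx] == site$peak_month]
        if (length(pk)) {
          ref <- as.list(met[pk[1], ])
        }
      }
      ref$ca <- mean(met$ca[idx], na.rm = TRUE)
      f_ref <- 1 - exp(-site$extinction[site$peak_month] * ref$lai)
      cap <- solve_one(ref, f_ref)
      out$vcmax25[idx] <- cap[1]; out$jmax25[idx] <- cap[2]; out$f_ref[idx] <- f_ref
    }
  } else { # monthly_ca, monthly_all
    for (i in seq_len(n)) {
      ref <- if (ts == "monthly_all") as.list(met[i, ]) else base_ref
      ref$ca <- met$ca[i]
      f_ref <- if (ts == "monthly_all") {
        1 - exp(-site$extinction[met$month[i]] * met$lai[i])
      } else {
        1 - exp(-site$extinction[site$peak_month] * base_ref$lai)
      }
      cap <- tryCatch(solve_one(ref, f_ref), error = function(e) c(NA_real_, NA_real_))
      out$vcmax25[i] <- cap[1]; out$jmax25[i] <- cap[2]; out$f_ref[i] <- f_ref
    }
  }
  out
}

#' Monthly canopy GPP
#'
#' Runs the full optimality chain (kinetics, water-cost ratio, optimal chi,
#' FvCB assimilation, Beer-Lambert upscaling, daytime integration) for every
#' month of a forcing table against a coordinated site model.
#'
#' @param met monthly forcing table (see [meteo_month()]), with `month` (and
#'   `year` for non-default coordination timescales).
#' @param site coordinated [site_model()] (see [coordinate_site()] or
#'   [calibrate_site()]).
#' @param cfg configuration from [eeo_config()].
#' @return `met` with appended columns `gpp` (gC m-2 mo-1), `a`
#'   (umol m-2 s-1), `chi`, `ci` (Pa), `g` (stomatal conductance,
#'   umol m-2 s-1 Pa-1), `iabs`, `beta_cost`, `limitation` and `missing`
#'   (months with incomplete drivers are flagged, not dropped).
#' @export
monthly_gpp <- function(met, site, cfg = eeo_config()) {
  validate_meteo(met)
  if (is.na(site$vcmax25_ref)) stop("site model is not coordinated; run coordinate_site()")
  drv <- c("ta", "swin", "p", "qa", "swc", "ca", "lai", "dayfrac", "ndays")
  ok <- stats::complete.cases(met[drv])
  caps <- .site_capacities(met, site, cfg)
  ok <- ok & is.finite(caps$vcmax25)
  out <- met
  out$gpp <- out$a <- out$chi <- out$ci <- out$g <- out$iabs <- out$beta_cost <- NA_real_
  out$limitation <- NA_character_
  out$missing <- !ok
  if (any(ok)) {
    m <- met[ok, ]
    res <- .gpp_core(m$ca, m$ta, m$swc, m$qa, m$swin, m$p, m$lai,
                     site$extinction[m$month], m$dayfrac, m$ndays,
                     caps$vcmax25[ok], caps$jmax25[ok], caps$f_ref[ok],
                     site$zeta0, site$pathway, cfg)
    out$gpp[ok] <- res$gpp
    out$a[ok] <- res$a
    out$chi[ok] <- res$chi
    out$ci[ok] <- res$ci
    out$g[ok] <- res$a / (res$ca_pp - res$ci)
    out$iabs[ok] <- res$iabs
    out$beta_cost[ok] <- res$beta_cost
    out$limitation[ok] <- res$limitation
  }
  out
}

#' Fraction of canopy GPP assimilated under light saturation
#'
#' @param gpp_df output of [monthly_gpp()].
#' @return fraction in [0, 1] of total GPP carried by Rubisco-limited
#'   (light-saturated) months.
#' @export
light_saturated_fraction <- function(gpp_df) {
  ok <- !is.na(gpp_df$gpp) & gpp_df$gpp > 0
  if (!any(ok)) return(NA_real_)
  sum(gpp_df$gpp[ok & gpp_df$limitation == "rubisco_limited"]) / sum(gpp_df$gpp[ok])
}

#' Calibrate a site model against reference GPP
#'
#' Least-squares fit of the 12 monthly light-extinction factors (pooled
#' across years by calendar month) and the water-cost constant zeta0 to a
#' reference monthly GPP series. Residuals are taken in log space (reference
#' GPP uncertainty is multiplicative); the coordination problem is re-solved
#' at every candidate parameter vector. Three deterministic multi-starts
#' guard against local minima; bounds are extinction in (0, 2] and
#' zeta0 > 0.
#'
#' @param met monthly forcing table with `year` and `month`.
#' @param ref_gpp reference GPP (gC m-2 mo-1), same length as `nrow(met)`;
#'   NAs and non-positive months are excluded from the fit.
#' @param pathway "C3" or "C4".
#' @param cfg configuration from [eeo_config()].
#' @param starts list of numeric start vectors `c(extinction, zeta0)`;
#'   defaults to three deterministic starts.
#' @return calibrated, coordinated `eeo_site` with attributes
#'   `rss` (residual sum of squares, log space), `n_obs`, and
#'   `unobserved_months` (calendar months that fell back to the fitted
#'   annual-mean extinction).
#' @export
calibrate_site <- function(met, ref_gpp, pathway = "C3", cfg = eeo_config(),
                           starts = NULL) {
  validate_meteo(met)
  stopifnot(length(ref_gpp) == nrow(met))
  use <- !is.na(ref_gpp) & ref_gpp > 0 &
    stats::complete.cases(met[c("ta", "swin", "p", "qa", "swc", "ca", "lai")])
  if (sum(use) < 12) stop("calibrate_site: need at least 12 months of overlapping reference GPP and drivers")
  if (stats::sd(ref_gpp[use]) == 0) {
    warning("calibrate_site: reference GPP has zero variance; seasonality is unconstrained")
  }
  obs_months <- sort(unique(met$month[use]))
  lref <- log(ref_gpp[use])

  build_site <- function(par) {
    s <- site_model(extinction = par[1:12], zeta0 = par[13], pathway = pathway)
    coordinate_site(s, met, cfg)
  }
  resid_fun <- function(par) {
    s <- tryCatch(build_site(par), error = function(e) NULL)
    if (is.null(s)) return(rep(1e3, sum(use)))
    g <- monthly_gpp(met, s, cfg)$gpp[use]
    bad <- !is.finite(g) | g <= 0
    r <- lref
    r[!bad] <- log(g[!bad]) - lref[!bad]
    r[bad] <- 1e3
    r
  }
  if (is.null(starts)) {
    starts <- list(c(rep(0.3, 12), 0.08), c(rep(0.6, 12), 0.15), c(rep(1.0, 12), 0.25))
  }
  lower <- c(rep(1e-4, 12), 0.02)
  upper <- c(rep(2, 12), 0.6)
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, lower = lower, upper = upper, fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-15, ptol = 1e-15, gtol = 0)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("calibrate_site: optimizer failed from every start")
  if (best$info < 1 || best$info > 4) {
    stop("calibrate_site: no convergence (info = ", best$info,
         ", residual RMS = ", signif(sqrt(best$deviance / sum(use)), 4), ")")
  }
  par <- best$par
  unobserved <- setdiff(1:12, obs_months)
  if (length(unobserved)) par[unobserved] <- mean(par[obs_months])
  site <- build_site(par)
  attr(site, "rss") <- best$deviance
  attr(site, "n_obs") <- sum(use)
  attr(site, "unobserved_months") <- unobserved
  site
}

#' Aggregate monthly GPP to annual totals with growing-season gap rules
#'
#' Sums the 12 calendar months of each year. The growing season is the set
#' of calendar months whose climatological mean GPP exceeds the threshold.
#' A year with exactly one missing growing-season month is kept if a backup
#' (low-quality, unfiltered) value exists for that month, which is then used;
#' a year with more than `max_gap` missing growing-season months is excluded.
#' Missing months outside the growing season are filled with their
#' climatological mean.
#'
#' @param gpp_df data.frame with `year`, `month`, `gpp` and optionally
#'   `gpp_backup`.
#' @param gap_policy list with `gs_threshold` (gC m-2 mo-1, default 30) and
#'   `max_gap` (default 1).
#' @return data.frame with `year`, `gpp` (gC m-2 yr-1), `status`
#'   ("ok", "backfilled" or "excluded") and `n_gs_gaps`; excluded years have
#'   `gpp = NA`.
#' @export
annual_aggregate <- function(gpp_df, gap_policy = list()) {
  pol <- utils::modifyList(list(gs_threshold = 30, max_gap = 1), gap_policy)
  stopifnot(all(c("year", "month", "gpp") %in% names(gpp_df)))
  clim <- tapply(gpp_df$gpp, gpp_df$month, mean, na.rm = TRUE)
  clim[is.nan(clim)] <- 0
  gs_months <- as.integer(names(clim))[clim > pol$gs_threshold]
  years <- sort(unique(gpp_df$year))
  out <- data.frame(year = years, gpp = NA_real_, status = "excluded",
                    n_gs_gaps = NA_integer_)
  for (i in seq_along(years)) {
    yr <- gpp_df[gpp_df$year == years[i], ]
    vals <- stats::setNames(rep(NA_real_, 12), 1:12)
    vals[as.character(yr$month)] <- yr$gpp
    backup <- stats::setNames(rep(NA_real_, 12), 1:12)
    if ("gpp_backup" %in% names(yr)) backup[as.character(yr$month)] <- yr$gpp_backup
    gaps <- which(is.na(vals))
    gs_gaps <- intersect(gaps, gs_months)
    out$n_gs_gaps[i] <- length(gs_gaps)
    status <- "ok"
    if (length(gs_gaps) > pol$max_gap) {
      out$status[i] <- "excluded"
      next
    }
    if (length(gs_gaps)) {
      if (any(is.na(backup[gs_gaps]))) {
        out$status[i] <- "excluded"
        next
      }
      vals[gs_gaps] <- backup[gs_gaps]
      status <- "backfilled"
    }
    ngs_gaps <- setdiff(which(is.na(vals)), gs_months)
    vals[ngs_gaps] <- clim[as.character(ngs_gaps)]
    vals[is.na(vals)] <- 0
    out$gpp[i] <- sum(vals)
    out$status[i] <- status
  }
  out
}
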
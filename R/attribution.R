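## Univariate factorial attribution of GPP trends: each driver in turn keeps
## its observed time variation while the other six are pinned at their
## calendar-month climatology; the Theil-Sen trend of the resulting annual
## network GPP is that driver's contribution. The "Aggregated" trend is the
## exact sum of the per-factor contributions.

.clim_met <- function(met) {
  clim <- stats::aggregate(met[c("ta", "swin", "p", "qa", "swc", "ca", "lai",
                                 "dayfrac")],
                           by = list(month = met$month), FUN = mean, na.rm = TRUE)
  idx <- match(met$month, clim$month)
  out <- met
  for (v in c("ta", "swin", "p", "qa", "swc", "ca", "lai", "dayfrac")) {
    out[[v]] <- clim[[v]][idx]
  }
  out
}

.annual_sum <- function(met_gpp) {
  agg <- stats::aggregate(met_gpp["gpp"], by = list(year = met_gpp$year), FUN = sum)
  agg
}

#' Univariate trend and IAV attribution across a network of sites
#'
#' For every driver, re-runs the model with only that driver time-varying
#' (all others at their calendar-month climatology), aggregates each site's
#' annual GPP, forms the cross-site network mean anomaly series, and takes
#' its Mann-Kendall/Theil-Sen trend as the driver's contribution.
#' Also returns: the all-drivers model trend; the partial-derivative CO2
#' trend estimate (network mean of beta_CO2 at climatology times the CO2
#' trend) as a cross-check; the apparent and direct logarithmic CO2
#' response ratios (endpoints taken on the fitted trend lines of the
#' all-drivers and CO2-only network series); and per-site IAV
#' contributions, the product of the absolute partial derivative and one SD
#' of the detrended annual driver.
#'
#' @param drivers data.frame with `site`, `year`, `month` and the forcing
#'   columns of [meteo_month()], at least 5 years.
#' @param sites named list of coordinated [site_model()] objects keyed by
#'   site id.
#' @param cfg configuration from [eeo_config()].
#' @return object of class `eeo_attribution`: list with `contributions`
#'   (factor, trend, p_value), `aggregated`, `direct_trend`,
#'   `ca_partial_trend`, `beta_app_ln`, `beta_dir_ln`, `beta_co2` (per-site),
#'   `iav` (site x factor data.frame), and `network` (the annual network
#'   series of every run).
#' @export
attribute_trends <- function(drivers, sites, cfg = eeo_config()) {
  stopifnot(all(c("site", "year", "month") %in% names(drivers)))
  if (length(unique(drivers$year)) < 5) {
    stop("attribute_trends: need at least 5 years of drivers")
  }
  ids <- names(sites)
  runs <- c("all", .driver_names)
  per_site <- list()
  beta_site <- stats::setNames(numeric(length(ids)), ids)
  iav_rows <- list()
  for (id in ids) {
    met <- drivers[drivers$site == id, ]
    met <- met[order(met$year, met$month), ]
    clim <- .clim_met(met)
    ann <- list()
    for (r in runs) {
      mm <- clim
      if (r == "all") {
        mm <- met
      } else {
        mm[[r]] <- met[[r]]
      }
      ann[[r]] <- .annual_sum(monthly_gpp(mm, sites[[id]], cfg))
    }
    per_site[[id]] <- ann
    clim12 <- clim[!duplicated(clim$month), ]
    sens <- partials(clim12, sites[[id]], mode = "analytic", cfg = cfg)
    beta_site[id] <- sens[["d_ca"]]
    ann_driver <- stats::aggregate(met[.driver_names],
                                   by = list(year = met$year), FUN = mean)
    iv <- vapply(.driver_names, function(d) {
      abs(sens[[paste0("d_", d)]]) * iav(ann_driver[[d]], ann_driver$year)
    }, numeric(1))
    iav_rows[[id]] <- data.frame(site = id, factor = .driver_names,
                                 iav_contribution = unname(iv))
  }

  network_series <- function(run) {
    tab <- do.call(rbind, lapply(ids, function(id) {
      a <- per_site[[id]][[run]]
      data.frame(site = id, year = a$year, value = a$gpp)
    }))
    anomalies(tab)$network
  }
  netw <- lapply(stats::setNames(runs, runs), network_series)
  trends <- lapply(netw, function(nw) mann_kendall_sen(nw$anomaly, nw$year))

  contributions <- data.frame(
    factor = .driver_names,
    trend = vapply(.driver_names, function(d) trends[[d]]$slope, numeric(1)),
    p_value = vapply(.driver_names, function(d) trends[[d]]$p_value, numeric(1))
  )
  aggregated <- sum(contributions$trend)

  # partial-derivative CO2 estimate: network-mean beta_CO2 x CO2 trend
  ann_ca <- stats::aggregate(drivers["ca"], by = list(year = drivers$year),
                             FUN = mean)
  dca <- mann_kendall_sen(ann_ca$ca, ann_ca$year)$slope
  ca_partial_trend <- mean(beta_site) * dca

  # beta^ln endpoints on the fitted trend lines (robust to endpoint noise);
  # network GPP level = mean across sites of annual totals
  level <- function(run) {
    tab <- do.call(rbind, lapply(ids, function(id) per_site[[id]][[run]]))
    lv <- stats::aggregate(tab["gpp"], by = list(year = tab$year), FUN = mean)
    lv
  }
  beta_from_run <- function(run) {
    lv <- level(run)
    tr <- mann_kendall_sen(lv$gpp, lv$year)
    ys <- min(lv$year); ye <- max(lv$year)
    gs <- tr$intercept + tr$slope * ys
    ge <- tr$intercept + tr$slope * ye
    ca_tr <- mann_kendall_sen(ann_ca$ca, ann_ca$year)
    cs <- ca_tr$intercept + ca_tr$slope * ys
    ce <- ca_tr$intercept + ca_tr$slope * ye
    if (!is.finite(gs) || !is.finite(ge) || gs <= 0 || ge <= 0 ||
        cs == ce) {
      return(NA_real_)  # undefined without a CO2 change over the period
    }
    beta_ln(gs, ge, cs, ce)
  }
  structure(list(
    contributions = contributions,
    aggregated = aggregated,
    direct_trend = trends[["all"]]$slope,
    direct_p = trends[["all"]]$p_value,
    ca_partial_trend = ca_partial_trend,
    beta_app_ln = beta_from_run("all"),
    beta_dir_ln = beta_from_run("ca"),
    beta_co2 = beta_site,
    iav = do.call(rbind, iav_rows),
    network = netw
  ), class = "eeo_attribution")
}

#' @export
print.eeo_attribution <- function(x, ...) {
  cat("Network GPP trend attribution (gC m-2 yr-2)\n")
  cat(sprintf("  model (all drivers): %.3f (p = %.3g)\n", x$direct_trend, x$direct_p))
  cat(sprintf("  aggregated:          %.3f\n", x$aggregated))
  for (i in seq_len(nrow(x$contributions))) {
    cat(sprintf("    %-5s %8.3f  (p = %.3g)\n", x$contributions$factor[i],
                x$contributions$trend[i], x$contributions$p_value[i]))
  }
  cat(sprintf("  CO2 via partial derivative: %.3f\n", x$ca_partial_trend))
  cat(sprintf("  beta_app_ln = %.3f, beta_dir_ln = %.3f\n",
              x$beta_app_ln, x$beta_dir_ln))
  invisible(x)
}

#' Tidy attribution table
#'
#' @param x an `eeo_attribution`.
#' @param ... unused.
#' @return data.frame: factor, contribution, p_value, method.
#' @export
as.data.frame.eeo_attribution <- function(x, ...) {
  rbind(
    data.frame(factor = x$contributions$factor,
               contribution = x$contributions$trend,
               p_value = x$contributions$p_value,
               method = "univariate"),
    data.frame(factor = "ca", contribution = x$ca_partial_trend,
               p_value = NA_real_, method = "partial_derivative")
  )
}
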
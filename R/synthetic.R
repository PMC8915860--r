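## Synthetic flux-network, fixture and grid generators. These emulate the
## statistical structure the analysis assumes -- seasonal cycles, a secular
## CO2 ramp (shared across sites, well-mixed atmosphere), slow warming,
## AR(1) interannual anomalies, quality-flag corruption, and partitioning
## spread on the reference GPP -- so that every pipeline stage is testable
## end-to-end without downloads. Every stochastic operation is a pure
## function of (config, seed).

#' Synthetic-data configuration
#'
#' @param preset "site-network" (default; CO2 ramp plus mild warming),
#'   "ca-only" (CO2 is the only trending driver; all else stationary),
#'   "grid" (latitudinal climate gradient with a C4 mask) or "fixture"
#'   (single site, short period, for half-hourly record generation).
#' @param ... named overrides of any field.
#' @return list of class `synth_config`. Fields: `n_sites`, `years`,
#'   `ca_start` (ppm), `ca_trend` (ppm yr-1), `ca_seas_amp` (ppm),
#'   `warming` (K yr-1), `ar1` (AR(1) coefficient of monthly anomalies),
#'   `noise` (per-driver SDs: `ta` K, `swin` W m-2, `swc` m3 m-3, `rh`
#'   [-], `lai_rel` relative), `gpp_noise_sdlog` (lognormal partitioning
#'   spread per variant-month), `variant_bias` (4 multiplicative biases),
#'   `qc_corrupt` (per-timestamp corruption probability), `c4_frac`
#'   (fraction of C4 grid cells), `nlat`, `nlon`.
#' @export
synth_config <- function(preset = c("site-network", "ca-only", "grid", "fixture"),
                         ...) {
  preset <- match.arg(preset)
  cfg <- list(
    preset = preset,
    n_sites = 20,
    years = 2001:2014,
    ca_start = 370, ca_trend = 2, ca_seas_amp = 2,
    warming = 0.03,
    ar1 = 0.3,
    noise = list(ta = 0.5, swin = 8, swc = 0.015, rh = 0.03, lai_rel = 0.03),
    gpp_noise_sdlog = 0.05,
    variant_bias = c(0.97, 1.01, 0.99, 1.03),
    qc_corrupt = 0.05,
    c4_frac = 0.12,
    nlat = 10, nlon = 10
  )
  if (preset == "ca-only") cfg$warming <- 0
  if (preset == "fixture") { cfg$n_sites <- 1; cfg$years <- 2001:2002 }
  ov <- list(...)
  for (nm in names(ov)) cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(ov[[nm]]))
    utils::modifyList(cfg[[nm]], ov[[nm]]) else ov[[nm]]
  stopifnot(abs(cfg$ar1) < 1, all(unlist(cfg$noise) >= 0))
  class(cfg) <- "synth_config"
  cfg
}

# deterministic static site properties spanning a temperate climate gradient
# (u: cool<->warm index, w: dry<->moist index, decoupled)
.site_props <- function(cfg) {
  n <- cfg$n_sites
  i <- seq_len(n)
  u <- if (n > 1) (i - 1) / (n - 1) else 0.5
  w <- ((i * 7) %% n) / max(n - 1, 1)
  w <- pmin(w, 1)
  data.frame(
    site = sprintf("S%02d", i), u = u, w = w,
    ta_mean = 8 + 14 * u, ta_amp = 13 - 6 * u,
    swin_mean = 150 + 70 * u, swin_amp = 110 - 50 * u,
    swc_mean = 0.12 + 0.18 * w, swc_amp = 0.035,
    rh_mean = 0.55 + 0.25 * w,
    lai_min = 0.3, lai_max = 1.2 + 2.3 * w,
    p = 101325 * exp(-(100 + 500 * (1 - u)) / 8500),
    dayfrac_amp = 0.05 + 0.1 * (1 - u),
    zeta0 = 0.06 + 0.18 * w,   # stress midpoint tracks site wetness (texture)
    ext_base = 0.45 + 0.2 * u,
    stringsAsFactors = FALSE
  )
}

#' True (generator) site models
#'
#' The per-site extinction climatology and water-cost constants used to
#' generate synthetic truth GPP; the targets of calibration-recovery
#' experiments. Deterministic given the configuration.
#'
#' @param cfg a [synth_config()].
#' @return named list of uncoordinated [site_model()] objects.
#' @export
synth_true_sites <- function(cfg) {
  pr <- .site_props(cfg)
  out <- lapply(seq_len(nrow(pr)), function(i) {
    ext <- pr$ext_base[i] + 0.1 * cos(2 * pi * ((1:12) - 1) / 12)
    site_model(extinction = ext, zeta0 = pr$zeta0[i], pathway = "C3")
  })
  stats::setNames(out, pr$site)
}

.ar1_noise <- function(n, sd, rho) {
  if (sd == 0) return(numeric(n))
  as.numeric(stats::filter(stats::rnorm(n, 0, sd * sqrt(1 - rho^2)),
                           rho, method = "recursive"))
}

.seas <- function(m, phase) cos(2 * pi * (m - phase) / 12)

.month_ndays <- c(31, 28.25, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)

#' Generate monthly forcing for a synthetic site network
#'
#' Seasonal sinusoids plus linear trends plus AR(1) anomalies per driver;
#' the CO2 series (deterministic ramp plus seasonal cycle) is shared across
#' sites. Physically plausible ranges are enforced by clamping.
#'
#' @param cfg a [synth_config()].
#' @param seed integer RNG seed (mandatory).
#' @return forcing data.frame (`site`, `year`, `month`, drivers, `dayfrac`,
#'   `ndays`), suitable for [monthly_gpp()] site by site.
#' @export
gen_forcing <- function(cfg, seed) {
  if (missing(seed)) stop("gen_forcing: `seed` is mandatory")
  set.seed(seed)
  pr <- .site_props(cfg)
  years <- cfg$years
  grid <- expand.grid(month = 1:12, year = years)
  m <- grid$month; yy <- grid$year - years[1]
  n <- nrow(grid)
  ca <- cfg$ca_start + cfg$ca_trend * (yy + (m - 0.5) / 12) +
    cfg$ca_seas_amp * .seas(m, 5)
  out <- vector("list", nrow(pr))
  for (i in seq_len(nrow(pr))) {
    s <- pr[i, ]
    ta <- s$ta_mean + s$ta_amp * .seas(m, 7) + cfg$warming * yy +
      .ar1_noise(n, cfg$noise$ta, cfg$ar1)
    swin <- pmax(s$swin_mean + s$swin_amp * .seas(m, 7) +
                   .ar1_noise(n, cfg$noise$swin, cfg$ar1), 5)
    swc <- pmin(pmax(s$swc_mean + s$swc_amp * .seas(m, 4) +
                       .ar1_noise(n, cfg$noise$swc, cfg$ar1), 0.02), 0.6)
    rh <- pmin(pmax(s$rh_mean + 0.05 * .seas(m, 1) +
                      .ar1_noise(n, cfg$noise$rh, cfg$ar1), 0.25), 0.95)
    qa <- vpd_to_q((1 - rh) * esat_pa(ta), ta, s$p)
    lai <- pmax((s$lai_min + (s$lai_max - s$lai_min) * 0.5 * (1 + .seas(m, 7))) *
                  (1 + .ar1_noise(n, cfg$noise$lai_rel, cfg$ar1)), 0.05)
    dayfrac <- pmin(pmax(0.5 + s$dayfrac_amp * .seas(m, 7), 0.25), 0.8)
    out[[i]] <- data.frame(site = s$site, year = grid$year, month = m,
                           ta = ta, swin = swin, p = s$p, qa = qa, swc = swc,
                           ca = ca, lai = lai, dayfrac = dayfrac,
                           ndays = .month_ndays[m])
  }
  do.call(rbind, out)
}

#' Generate half-hourly FLUXNET-style records
#'
#' Expands one synthetic site's monthly forcing into half-hourly records
#' with diurnal shortwave/temperature/VPD cycles (constructed so the monthly
#' daytime means match the generating forcing), nighttime flags, four GPP
#' variants (model truth distributed over daytime slots, per-variant
#' multiplicative bias plus lognormal monthly partitioning noise), and
#' quality flags corrupted at a configured per-timestamp rate.
#'
#' @param cfg a [synth_config()] (preset "fixture" recommended).
#' @param seed integer RNG seed.
#' @param site_index which synthetic site to expand (default 1).
#' @param qc_corrupt baseline per-timestamp corruption probability.
#' @param corrupt_months optional named numeric, e.g. `c("6" = 0.6)`,
#'   overriding the corruption rate in given calendar months.
#' @return data.frame of half-hourly records (FLUXNET FULLSET column
#'   names); attributes `truth` (monthly truth table with `gpp`), `site`
#'   (the coordinated true site model) and `forcing` (the monthly forcing).
#' @export
gen_flux_fixture <- function(cfg, seed, site_index = 1,
                             qc_corrupt = cfg$qc_corrupt,
                             corrupt_months = NULL) {
  forcing <- gen_forcing(cfg, seed)
  ids <- unique(forcing$site)
  met <- forcing[forcing$site == ids[site_index], ]
  true_site <- synth_true_sites(cfg)[[ids[site_index]]]
  true_site <- coordinate_site(true_site, met, eeo_config())
  truth <- monthly_gpp(met, true_site, eeo_config())

  set.seed(seed + 1)
  rows <- vector("list", nrow(truth))
  for (r in seq_len(nrow(truth))) {
    tm <- truth[r, ]
    nd <- .days_in_month(tm$year, tm$month)
    n_day_slots <- max(4, round(tm$dayfrac * 48))
    first <- floor((48 - n_day_slots) / 2) + 1
    slots <- 1:48
    is_day <- slots >= first & slots < first + n_day_slots
    wsin <- numeric(48)
    wsin[is_day] <- sin(pi * (seq_len(n_day_slots) - 0.5) / n_day_slots)
    sw <- numeric(48)
    sw[is_day] <- tm$swin * wsin[is_day] / mean(wsin[is_day])
    diel <- cos(2 * pi * (slots - 30) / 48)
    ta <- tm$ta + 2 * (diel - mean(diel[is_day]))
    vpd_m <- q_to_vpd(tm$qa, tm$ta, tm$p)  # Pa
    vpd <- rep(vpd_m * 0.3, 48)
    vpd[is_day] <- vpd_m * wsin[is_day] / mean(wsin[is_day])
    # distribute the monthly truth mass over daytime slots, proportional to SW
    tot_umol <- tm$gpp / 12.011e-6
    flux <- numeric(48)
    flux[is_day] <- tot_umol * (wsin[is_day] / sum(wsin[is_day])) / (nd * 1800)
    vb <- cfg$variant_bias * exp(stats::rnorm(4, 0, cfg$gpp_noise_sdlog))
    rate <- qc_corrupt
    if (!is.null(corrupt_months) && as.character(tm$month) %in% names(corrupt_months)) {
      rate <- corrupt_months[[as.character(tm$month)]]
    }
    day_rows <- vector("list", nd)
    for (dd in seq_len(nd)) {
      qc <- matrix(0L, 48, 3)
      hit <- stats::runif(48) < rate
      which_var <- sample.int(3, 48, replace = TRUE)
      qc[cbind(which(hit), which_var[hit])] <- 2L
      day_rows[[dd]] <- data.frame(
        TIMESTAMP_START = sprintf("%04d%02d%02d%02d%02d", tm$year, tm$month,
                                  dd, (slots - 1) %/% 2, ((slots - 1) %% 2) * 30),
        TA_F = ta, TA_F_QC = qc[, 1],
        SW_IN_F = sw, SW_IN_F_QC = qc[, 2],
        VPD_F = vpd / 100, VPD_F_QC = qc[, 3],       # hPa
        PA_F = tm$p / 1000,                          # kPa
        SWC_F_MDS_1 = tm$swc * 100,                  # percent
        NIGHT = as.integer(!is_day),
        GPP_NT_VUT_MEAN = flux * vb[1],
        GPP_DT_VUT_MEAN = flux * vb[2],
        GPP_NT_CUT_MEAN = flux * vb[3],
        GPP_DT_CUT_MEAN = flux * vb[4]
      )
    }
    rows[[r]] <- do.call(rbind, day_rows)
  }
  rec <- do.call(rbind, rows)
  attr(rec, "truth") <- truth
  attr(rec, "site") <- true_site
  attr(rec, "forcing") <- met
  rec
}

.days_in_month <- function(year, month) {
  as.integer(format(seq(as.Date(sprintf("%04d-%02d-01", year, month)),
                        by = "month", length.out = 2)[2] - 1, "%d"))
}

#' Generate a small gridded forcing with a C4 mask
#'
#' A latitude-by-moisture climate gradient (hot and humid in the low-index
#' corner, cold at high latitude, dry at low moisture index) with monthly
#' forcing over the configured years. The hottest, driest cells are labeled
#' C4, with the masked fraction equal to `cfg$c4_frac` exactly.
#'
#' @param cfg a [synth_config()] (preset "grid" recommended).
#' @param seed integer RNG seed.
#' @return list with `cells` (cell, lat, lon index, c4 flag, climatology
#'   summaries) and `drivers` (long forcing table keyed by `cell`).
#' @export
gen_grid <- function(cfg, seed) {
  if (missing(seed)) stop("gen_grid: `seed` is mandatory")
  set.seed(seed)
  lat <- seq(0, 60, length.out = cfg$nlat)
  wv <- seq(0.15, 1, length.out = cfg$nlon)
  cells <- expand.grid(ilat = seq_len(cfg$nlat), ilon = seq_len(cfg$nlon))
  cells$lat <- lat[cells$ilat]
  cells$w <- wv[cells$ilon]
  cells$cell <- sprintf("G%03d", seq_len(nrow(cells)))
  cells$ta_mean <- 27 - 0.38 * cells$lat
  cells$score_c4 <- cells$ta_mean - 18 * cells$w   # hot and dry
  nc4 <- round(cfg$c4_frac * nrow(cells))
  cells$c4 <- rank(-cells$score_c4, ties.method = "first") <= nc4
  years <- cfg$years
  grid <- expand.grid(month = 1:12, year = years)
  m <- grid$month; yy <- grid$year - years[1]
  n <- nrow(grid)
  ca <- cfg$ca_start + cfg$ca_trend * (yy + (m - 0.5) / 12) +
    cfg$ca_seas_amp * .seas(m, 5)
  drv <- lapply(seq_len(nrow(cells)), function(i) {
    cc <- cells[i, ]
    ta_amp <- 2 + 0.18 * cc$lat
    ta <- cc$ta_mean + ta_amp * .seas(m, 7) + .ar1_noise(n, cfg$noise$ta, cfg$ar1)
    swin <- pmax(250 - 1.5 * cc$lat + (25 + 1.2 * cc$lat) * .seas(m, 7) +
                   .ar1_noise(n, cfg$noise$swin, cfg$ar1), 5)
    swc <- pmin(pmax(0.08 + 0.24 * cc$w + 0.03 * .seas(m, 4) +
                       .ar1_noise(n, cfg$noise$swc, cfg$ar1), 0.02), 0.6)
    rh <- pmin(pmax(0.45 + 0.35 * cc$w + .ar1_noise(n, cfg$noise$rh, cfg$ar1),
                    0.25), 0.95)
    qa <- vpd_to_q((1 - rh) * esat_pa(ta), ta, 101325)
    lai <- pmax((0.4 + 3.6 * cc$w) * 0.5 * (1 + 0.8 * .seas(m, 7)), 0.05)
    dayfrac <- pmin(pmax(0.5 + 0.004 * cc$lat * .seas(m, 7), 0.25), 0.8)
    data.frame(cell = cc$cell, year = grid$year, month = m, ta = ta,
               swin = swin, p = 101325, qa = qa, swc = swc, ca = ca,
               lai = lai, dayfrac = dayfrac, ndays = .month_ndays[m])
  })
  list(cells = cells[c("cell", "ilat", "ilon", "lat", "w", "ta_mean", "c4")],
       drivers = do.call(rbind, drv))
}

#' CO2 sensitivity map over a synthetic grid
#'
#' Coordinates a default canopy model in every cell (extinction 0.5,
#' default water-cost constant, pathway from the C4 mask) and evaluates the
#' analytic annual beta_CO2 at the cell's monthly climatology.
#'
#' @param grid output of [gen_grid()].
#' @param cfg configuration from [eeo_config()].
#' @param extinction,zeta0 canopy constants applied to every cell.
#' @return `grid$cells` with an added `beta_co2` column
#'   (gC m-2 yr-1 ppm-1).
#' @export
beta_co2_map <- function(grid, cfg = eeo_config(), extinction = 0.5,
                         zeta0 = eeo_config()$mwue$zeta0) {
  cells <- grid$cells
  cells$beta_co2 <- NA_real_
  for (i in seq_len(nrow(cells))) {
    met <- grid$drivers[grid$drivers$cell == cells$cell[i], ]
    clim <- .clim_met(met)
    clim12 <- clim[!duplicated(clim$month), ]
    clim12$ndays <- .month_ndays[clim12$month]
    site <- site_model(rep(extinction, 12), zeta0,
                       pathway = if (cells$c4[i]) "C4" else "C3")
    site <- coordinate_site(site, met, cfg)
    cells$beta_co2[i] <- partials(clim12, site, "analytic", cfg)[["d_ca"]]
  }
  cells
}

#' Write records in FLUXNET-style CSV
#'
#' @param records data.frame of records.
#' @param path output file.
#' @export
write_fluxnet_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
}

#' Write a two-column monthly CO2 series
#'
#' `date,ppm` text format (observatory-style monthly means).
#'
#' @param forcing forcing table with `year`, `month`, `ca`.
#' @param path output file.
#' @export
write_co2_csv <- function(forcing, path) {
  u <- forcing[!duplicated(paste(forcing$year, forcing$month)), ]
  utils::write.csv(data.frame(date = sprintf("%04d-%02d", u$year, u$month),
                              ppm = u$ca), path, row.names = FALSE, quote = FALSE)
}
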
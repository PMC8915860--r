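# Shared fixtures, built once per run. Seed 101 is the suite-wide fixture
# seed; individual property tests that need independent draws derive their
# own seeds locally.

fx_cfg <- eeo_config()
fx_sc <- synth_config()
fx_forcing <- gen_forcing(fx_sc, seed = 101)

fx_site_cache <- new.env(parent = emptyenv())

# coordinated true site model for a generator site id
fx_site <- function(id = "S10") {
  if (is.null(fx_site_cache[[id]])) {
    met <- fx_forcing[fx_forcing$site == id, ]
    fx_site_cache[[id]] <- coordinate_site(synth_true_sites(fx_sc)[[id]],
                                           met, fx_cfg)
  }
  fx_site_cache[[id]]
}

fx_met <- function(id = "S10") fx_forcing[fx_forcing$site == id, ]

# one climatological year (calendar-month means) for a site
fx_clim12 <- function(id = "S10") {
  met <- fx_met(id)
  clim <- aggregate(met[c("ta", "swin", "p", "qa", "swc", "ca", "lai",
                          "dayfrac", "ndays")],
                    by = list(month = met$month), FUN = mean)
  clim$year <- 0
  clim[order(clim$month), ]
}

# random single-month environments over realistic ranges (rows independent)
rand_env <- function(n, seed) {
  set.seed(seed)
  ta <- runif(n, 4, 35)
  p <- runif(n, 80000, 101325)
  rh <- runif(n, 0.35, 0.9)
  data.frame(year = 0, month = sample.int(12, n, replace = TRUE),
             ta = ta, swin = runif(n, 60, 320), p = p,
             qa = vpd_to_q((1 - rh) * esat_pa(ta), ta, p),
             swc = runif(n, 0.05, 0.45), ca = runif(n, 360, 700),
             lai = runif(n, 0.3, 5), dayfrac = runif(n, 0.35, 0.65),
             ndays = 30.44)
}

# independent brute-force minimizer of the least-cost criterion on a dense
# two-stage ci grid (the optimality oracle)
chi_bruteforce <- function(ca_pp, d, kin, beta_cost, cfg = fx_cfg) {
  d <- max(d, cfg$water$d_floor)
  cost <- function(ci) {
    1.6 * kin$eta_star * d / (ca_pp - ci) +
      beta_cost * (ci + kin$K) / (ci - kin$gamma_star)
  }
  lo <- kin$gamma_star * 1.0001
  hi <- ca_pp * 0.99999
  g1 <- seq(lo, hi, length.out = 3000)
  i1 <- which.min(cost(g1))
  lo2 <- g1[max(i1 - 1, 1)]; hi2 <- g1[min(i1 + 1, length(g1))]
  g2 <- seq(lo2, hi2, length.out = 3000)
  g2[which.min(cost(g2))]
}

# hand-made half-hourly records: one month, `n_days` days, `n_day_slots`
# daytime slots per day, with a prescribed number of QC-bad daytime stamps
make_month_records <- function(year, month, n_days, n_day_slots, n_bad = 0,
                               gpp = 5) {
  slots <- 1:48
  first <- floor((48 - n_day_slots) / 2) + 1
  is_day <- slots >= first & slots < first + n_day_slots
  rows <- do.call(rbind, lapply(seq_len(n_days), function(dd) {
    data.frame(
      TIMESTAMP_START = sprintf("%04d%02d%02d%02d%02d", year, month, dd,
                                (slots - 1) %/% 2, ((slots - 1) %% 2) * 30),
      TA_F = 15, TA_F_QC = 0L, SW_IN_F = ifelse(is_day, 400, 0),
      SW_IN_F_QC = 0L, VPD_F = 8, VPD_F_QC = 0L, PA_F = 101.325,
      SWC_F_MDS_1 = 25, NIGHT = as.integer(!is_day),
      GPP_NT_VUT_MEAN = ifelse(is_day, gpp, 0),
      GPP_DT_VUT_MEAN = ifelse(is_day, gpp, 0),
      GPP_NT_CUT_MEAN = ifelse(is_day, gpp, 0),
      GPP_DT_CUT_MEAN = ifelse(is_day, gpp, 0)
    )
  }))
  if (n_bad > 0) {
    day_idx <- which(rows$NIGHT == 0)
    rows$VPD_F_QC[day_idx[seq_len(n_bad)]] <- 2L
  }
  rows
}
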
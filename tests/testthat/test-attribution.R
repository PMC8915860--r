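# Small (6-site) networks keep the unit suite fast; the acceptance suite
# runs the full 20-site experiment.

small_network <- function(preset, seed) {
  sc <- synth_config(preset, n_sites = 6)
  f <- gen_forcing(sc, seed)
  sites <- synth_true_sites(sc)
  sites <- lapply(names(sites), function(id) {
    coordinate_site(sites[[id]], f[f$site == id, ], fx_cfg)
  })
  names(sites) <- sprintf("S%02d", 1:6)
  list(forcing = f, sites = sites)
}

test_that("a CO2-only trending network attributes the trend to CO2", {
  nw <- small_network("ca-only", seed = 41)
  att <- attribute_trends(nw$forcing, nw$sites, fx_cfg)
  expect_equal(att$aggregated, sum(att$contributions$trend))   # exact additivity
  ca_row <- att$contributions[att$contributions$factor == "ca", ]
  expect_gt(ca_row$trend / att$aggregated, 0.9)
  expect_lt(ca_row$p_value, 0.01)
  # partial-derivative CO2 estimate agrees with the univariate estimate
  expect_lt(abs(att$ca_partial_trend - ca_row$trend) / ca_row$trend, 0.15)
  expect_gt(att$beta_dir_ln, 0)
})

test_that("a trend-free network yields no significant contributions", {
  nw <- small_network("ca-only", seed = 42)
  f <- nw$forcing
  # freeze the CO2 ramp too: stationary everything
  f$ca <- fx_sc$ca_start + 2 * eeogpp:::.seas(f$month, 5)
  att <- attribute_trends(f, nw$sites, fx_cfg)
  expect_true(all(abs(att$contributions$trend) < 0.6))
  expect_gte(sum(att$contributions$p_value > 0.05), 6)
})

test_that("CO2 sensitivity is positive for C3 and much weaker for matched C4", {
  met <- fx_met("S12")
  clim <- fx_clim12("S12")
  s3 <- coordinate_site(site_model(rep(0.5, 12), 0.12, "C3"), met, fx_cfg)
  s4 <- coordinate_site(site_model(rep(0.5, 12), 0.12, "C4"), met, fx_cfg)
  b3 <- partials(clim, s3, "analytic")[["d_ca"]]
  b4 <- partials(clim, s4, "analytic")[["d_ca"]]
  expect_gt(b4, 0)
  expect_lt(b4, b3 / 2)
})

test_that("IAV contributions are the product of |partial| and detrended driver SD", {
  nw <- small_network("site-network", seed = 43)
  att <- attribute_trends(nw$forcing, nw$sites, fx_cfg)
  iv <- att$iav
  expect_true(all(iv$iav_contribution >= 0))
  # independent recomputation for one site/factor
  id <- "S03"
  met <- nw$forcing[nw$forcing$site == id, ]
  clim <- met
  for (v in c("ta", "swin", "p", "qa", "swc", "ca", "lai", "dayfrac")) {
    clim[[v]] <- ave(met[[v]], met$month)
  }
  clim12 <- clim[!duplicated(clim$month), ]
  sens <- partials(clim12, nw$sites[[id]], "analytic")
  ann_swc <- tapply(met$swc, met$year, mean)
  want <- abs(sens[["d_swc"]]) * iav(as.numeric(ann_swc), as.numeric(names(ann_swc)))
  got <- iv$iav_contribution[iv$site == id & iv$factor == "swc"]
  expect_equal(got, want, tolerance = 1e-8)
})
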
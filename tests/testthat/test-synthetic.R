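test_that("every stochastic generator is a pure function of (config, seed)", {
  sc <- synth_config(n_sites = 3, years = 2001:2004)
  expect_identical(gen_forcing(sc, 77), gen_forcing(sc, 77))
  expect_false(identical(gen_forcing(sc, 77)$ta, gen_forcing(sc, 78)$ta))
  scg <- synth_config("grid", nlat = 4, nlon = 4, years = 2001:2002)
  expect_identical(gen_grid(scg, 5)$drivers, gen_grid(scg, 5)$drivers)
})

test_that("the generated CO2 ramp has exactly the configured trend", {
  f <- fx_forcing[fx_forcing$site == "S01", ]
  ann_ca <- tapply(f$ca, f$year, mean)
  sl <- mann_kendall_sen(as.numeric(ann_ca), as.numeric(names(ann_ca)))$slope
  expect_equal(sl, fx_sc$ca_trend, tolerance = 1e-6)
  # shared across sites (well-mixed atmosphere)
  f2 <- fx_forcing[fx_forcing$site == "S02", ]
  expect_identical(f$ca, f2$ca)
})

test_that("the AR(1) coefficient of driver anomalies is recoverable by Yule-Walker", {
  sc <- synth_config(n_sites = 1, years = 1971:2020, warming = 0)
  f <- gen_forcing(sc, 99)
  anom <- f$ta - ave(f$ta, f$month)   # deseasonalize
  fit <- stats::ar(anom, order.max = 1, method = "yule-walker", aic = FALSE)
  expect_lt(abs(fit$ar - sc$ar1), 0.1)
})

test_that("generated forcing respects physical ranges", {
  f <- fx_forcing
  expect_true(all(f$swin >= 0))
  expect_true(all(f$swc >= 0 & f$swc <= 1))
  expect_true(all(f$lai >= 0))
  expect_true(all(q_to_vpd(f$qa, f$ta, f$p) > 0))
  expect_true(all(f$dayfrac > 0 & f$dayfrac < 1))
})

test_that("the synthetic grid has the right climate structure and exact C4 fraction", {
  sc <- synth_config("grid", years = 2001:2002)
  gr <- gen_grid(sc, 13)
  cells <- gr$cells
  eq <- cells$ta_mean[cells$ilat == 1]
  pole <- cells$ta_mean[cells$ilat == max(cells$ilat)]
  expect_true(all(outer(eq, pole, ">")))
  expect_equal(mean(cells$c4), sc$c4_frac)
  # C4 cells concentrate in the hot, dry corner
  expect_gt(mean(cells$ta_mean[cells$c4]), mean(cells$ta_mean[!cells$c4]))
  expect_lt(mean(cells$w[cells$c4]), mean(cells$w[!cells$c4]))
})

test_that("half-hourly fixtures aggregate back to their generating forcing", {
  sc <- synth_config("fixture", years = 2001)
  rec <- gen_flux_fixture(sc, 15, qc_corrupt = 0)
  expect_true(all(qc_filter(rec)$qc_pass))  # zero corruption masks nothing
  mq <- fluxprep_monthly(rec)
  forc <- attr(rec, "forcing")
  truth <- attr(rec, "truth")
  i <- match(paste(mq$year, mq$month), paste(forc$year, forc$month))
  expect_lt(max(abs(mq$TA_F - forc$ta[i])), 1e-9)
  expect_lt(max(abs(mq$SW_IN_F - forc$swin[i]) / forc$swin[i]), 0.02)
  vpd <- q_to_vpd(forc$qa[i], forc$ta[i], forc$p[i])
  expect_lt(max(abs(mq$VPD_F * 100 - vpd) / vpd), 0.02)
  # reference GPP carries only the configured partitioning spread
  expect_lt(max(abs(mq$gpp_ref - truth$gpp[i]) / truth$gpp[i]),
            4 * sc$gpp_noise_sdlog / sqrt(4))
  # heavy corruption of one month drives it below the 50% threshold
  rec2 <- gen_flux_fixture(sc, 15, corrupt_months = c("6" = 0.6))
  mq2 <- fluxprep_monthly(rec2)
  expect_false(any(mq2$retained[mq2$month == 6]))
  expect_true(all(mq2$retained[mq2$month != 6]))
})

test_that("fixture and CO2 writers emit readable delimited text", {
  sc <- synth_config("fixture", years = 2001)
  rec <- gen_flux_fixture(sc, 15)
  tf <- tempfile(fileext = ".csv")
  write_fluxnet_csv(rec[1:100, ], tf)
  back <- read_fluxnet(tf)
  expect_equal(back$TA_F, rec$TA_F[1:100], tolerance = 1e-9)
  tf2 <- tempfile(fileext = ".csv")
  write_co2_csv(attr(rec, "forcing"), tf2)
  co2 <- utils::read.csv(tf2)
  expect_identical(nrow(co2), 12L)
  expect_true(all(co2$ppm > 300))
})
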
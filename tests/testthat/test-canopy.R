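test_that("Beer-Lambert absorption: zero at zero LAI, saturating, diminishing returns", {
  expect_identical(absorbed_light(300, 0, 0.5), 0)
  frac <- function(lai) 1 - exp(-0.5 * lai)
  expect_gt(frac(50), 0.999)
  d_at <- function(lai, h = 1e-4) {
    (absorbed_light(300, lai + h, 0.5) - absorbed_light(300, lai - h, 0.5)) / (2 * h)
  }
  expect_lt(d_at(6), d_at(0.5) / 10)
})

test_that("monthly GPP is zero without light or leaves, positive otherwise, and Fick-consistent", {
  site <- fx_site("S10")
  met <- fx_clim12("S10")
  g <- monthly_gpp(met, site, fx_cfg)
  expect_true(all(g$gpp > 0))
  m0 <- met[7, ]; m0$lai <- 0
  expect_equal(monthly_gpp(m0, site, fx_cfg)$gpp, 0, tolerance = 1e-12)
  mdark <- met[7, ]; mdark$swin <- 0; mdark$dayfrac <- 0
  expect_equal(monthly_gpp(mdark, site, fx_cfg)$gpp, 0, tolerance = 1e-12)
  # Fick consistency of the solved leaf states
  ca_pp <- g$ca * 1e-6 * g$p
  expect_lt(max(abs(g$a - g$g * (ca_pp - g$ci)) / pmax(g$a, 1e-9)), 1e-10)
})

test_that("GPP is non-decreasing in LAI, shortwave radiation and CO2 (C3)", {
  site <- fx_site("S10")
  base <- fx_clim12("S10")
  g0 <- monthly_gpp(base, site, fx_cfg)$gpp
  for (v in c("lai", "swin", "ca")) {
    up <- base
    up[[v]] <- up[[v]] * 1.05
    g1 <- monthly_gpp(up, site, fx_cfg)$gpp
    expect_true(all(g1 >= g0 - 1e-12), info = v)
  }
  up1 <- base; up1$ca <- up1$ca + 1
  expect_true(all(monthly_gpp(up1, site, fx_cfg)$gpp > g0))
})

test_that("finite-difference dGPP/dca matches the analytic beta_CO2", {
  # an actual (noisy) year: climatological months would place the reference
  # month exactly on the co-limitation kink, where the derivative is
  # one-sided by construction
  site <- fx_site("S10")
  met <- fx_met("S10")
  met <- met[met$year == 2005, ]
  d_an <- partials(met, site, "analytic")[["d_ca"]]
  up <- met; up$ca <- up$ca + 0.5
  dn <- met; dn$ca <- dn$ca - 0.5
  d_fd <- (sum(monthly_gpp(up, site, fx_cfg)$gpp) -
             sum(monthly_gpp(dn, site, fx_cfg)$gpp))
  expect_lt(abs(d_fd - d_an) / abs(d_an), 1e-5)
})

test_that("months with missing drivers are flagged, not dropped or raised", {
  site <- fx_site("S10")
  met <- fx_clim12("S10")
  met$swc[3] <- NA
  g <- monthly_gpp(met, site, fx_cfg)
  expect_identical(nrow(g), nrow(met))
  expect_true(g$missing[3])
  expect_true(is.na(g$gpp[3]))
  expect_false(any(g$missing[-3]))
})

test_that("light-saturation bookkeeping: bright sparse canopies saturate more than dim dense ones", {
  site <- fx_site("S10")
  met <- fx_clim12("S10")
  bright <- met; bright$swin <- met$swin * 1.6; bright$lai <- pmin(met$lai, 0.8)
  dim <- met; dim$swin <- met$swin * 0.4; dim$lai <- met$lai + 3
  fb <- light_saturated_fraction(monthly_gpp(bright, site, fx_cfg))
  fd <- light_saturated_fraction(monthly_gpp(dim, site, fx_cfg))
  expect_true(fb >= 0 && fb <= 1)
  expect_true(fd >= 0 && fd <= 1)
  expect_gt(fb, fd)
})

test_that("annual aggregation applies the growing-season gap rules", {
  base <- data.frame(year = rep(1:3, each = 12), month = rep(1:12, 3),
                     gpp = rep(100, 36))
  ann <- annual_aggregate(base)
  expect_equal(ann$gpp, rep(1200, 3))
  expect_equal(ann$status, rep("ok", 3))
  # year 2: one growing-season gap with a backup -> backfilled
  d <- base
  d$gpp_backup <- d$gpp * 0.9
  d$gpp[d$year == 2 & d$month == 6] <- NA
  ann <- annual_aggregate(d)
  expect_identical(ann$status[2], "backfilled")
  expect_equal(ann$gpp[2], 11 * 100 + 90)
  # year 3: two growing-season gaps -> excluded
  d$gpp[d$year == 3 & d$month %in% c(6, 7)] <- NA
  ann <- annual_aggregate(d)
  expect_identical(ann$status[3], "excluded")
  expect_true(is.na(ann$gpp[3]))
})
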
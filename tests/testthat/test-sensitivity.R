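test_that("algorithmic and finite-difference sensitivities agree on random environments", {
  site <- fx_site("S10")
  env <- rand_env(60, seed = 31)
  for (i in seq_len(nrow(env))) {
    m <- env[i, ]
    an <- partials(m, site, "analytic")
    fd <- partials(m, site, "finite_difference")
    scale <- pmax(abs(an), 1e-8)
    expect_lt(max(abs(an - fd) / scale), 1e-5)
  }
})

test_that("the five temperature pathways close the total temperature sensitivity", {
  site <- fx_site("S10")
  env <- rand_env(40, seed = 32)
  for (i in seq_len(nrow(env))) {
    m <- env[i, ]
    tp <- ta_pathways(m, site)
    d_ta <- partials(m, site, "analytic")[["d_ta"]]
    expect_lt(abs(tp[["total"]] - d_ta) / max(abs(d_ta), 1e-8), 1e-6)
    expect_lte(tp[["via_D"]], 0)  # warming raises demand, closing stomata
  }
})

test_that("a month with no daytime has identically zero sensitivities", {
  site <- fx_site("S10")
  m <- fx_clim12("S10")[1, ]
  m$swin <- 0
  m$dayfrac <- 0
  s <- partials(m, site, "analytic")
  expect_true(all(s == 0))
})

test_that("the composite first-order change reproduces the full model for small perturbations", {
  site <- fx_site("S10")
  met <- fx_clim12("S10")
  sens <- partials(met, site, "analytic")
  expect_identical(composite_change(sens, list())$total, 0)
  only_ca <- composite_change(sens, list(ca = 5))
  expect_equal(only_ca$total, sens[["d_ca"]] * 5)
  expect_equal(only_ca$direct_cfe, only_ca$total)
  # 0.1% perturbation of every driver: Taylor remainder below 1%
  eps <- 1e-3
  pert <- met
  deltas <- list()
  for (d in c("ca", "lai", "ta", "swc", "qa", "swin", "p")) {
    deltas[[d]] <- eps * mean(met[[d]])
    pert[[d]] <- pert[[d]] + deltas[[d]]
  }
  dg_model <- sum(monthly_gpp(pert, site, fx_cfg)$gpp) -
    sum(monthly_gpp(met, site, fx_cfg)$gpp)
  dg_comp <- composite_change(sens, deltas)$total
  expect_lt(abs(dg_model - dg_comp) / abs(dg_model), 0.01)
})

test_that("the logarithmic CO2 response ratio behaves per definition", {
  expect_identical(beta_ln(150, 150, 370, 407), 0)
  expect_equal(beta_ln(100, 110, 370, 407), 1, tolerance = 1e-12)
  expect_equal(beta_ln(100, 105, 370, 407), log(1.05) / log(407 / 370),
               tolerance = 1e-15)
  expect_error(beta_ln(-1, 100, 370, 407), "positive")
  expect_error(beta_ln(100, 100, 370, 370), "differ")
})

test_that("detrended-SD interannual variability behaves per definition", {
  expect_equal(iav(3 + 2 * (1:20)), 0, tolerance = 1e-12)
  set.seed(5)
  reps <- replicate(400, iav(rnorm(30, sd = 2)))
  expect_equal(mean(reps), 2, tolerance = 0.05)
  set.seed(6)
  noise <- replicate(200, { e <- rnorm(30, sd = 1.5); iav(10 + e) })
  set.seed(6)
  trended <- replicate(200, { e <- rnorm(30, sd = 1.5); iav(10 + 0.8 * (1:30) + e) })
  expect_equal(mean(trended), mean(noise), tolerance = 0.05)
})
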
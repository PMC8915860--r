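test_that("closed-form chi equals the brute-force least-cost minimum", {
  env <- rand_env(80, seed = 11)
  beta <- runif(80, 20, 400)
  for (i in seq_len(nrow(env))) {
    kin <- kinetics_at(env$ta[i], env$p[i])
    ca_pp <- env$ca[i] * 1e-6 * env$p[i]
    d <- q_to_vpd(env$qa[i], env$ta[i], env$p[i])
    opt <- optimal_chi(ca_pp, d, kin, beta[i])
    ci_bf <- chi_bruteforce(ca_pp, d, kin, beta[i])
    expect_lt(abs(ci_bf - opt$ci) / opt$ci, 1e-4)
  }
})

test_that("chi is decreasing in vapour pressure deficit and increasing in the cost ratio", {
  kin <- kinetics_at(20, 101325)
  ca_pp <- 420e-6 * 101325
  ds <- c(100, 400, 900, 1600, 2500)
  chis <- vapply(ds, function(d) optimal_chi(ca_pp, d, kin, 146)$chi, numeric(1))
  expect_true(all(diff(chis) < 0))
  betas <- c(20, 60, 146, 300)
  chib <- vapply(betas, function(b) optimal_chi(ca_pp, 1000, kin, b)$chi, numeric(1))
  expect_true(all(diff(chib) > 0))
})

test_that("chi approaches gamma*/ca in the infinite-demand limit", {
  kin <- kinetics_at(20, 101325)
  ca_pp <- 420e-6 * 101325
  opt <- optimal_chi(ca_pp, 1e14, kin, 146)
  expect_equal(opt$chi, kin$gamma_star / ca_pp, tolerance = 1e-3)
})

test_that("ci doubles exactly with ca when the compensation point is negligible", {
  kin <- kinetics_at(20, 101325)
  kin$gamma_star <- 1e-12
  o1 <- optimal_chi(40, 1000, kin, 146)
  o2 <- optimal_chi(80, 1000, kin, 146)
  expect_equal(o2$ci / o1$ci, 2, tolerance = 1e-9)
  expect_equal(o1$chi, o2$chi, tolerance = 1e-9)
})

test_that("vapour pressure deficit is clamped at the configured floor", {
  kin <- kinetics_at(20, 101325)
  ca_pp <- 420e-6 * 101325
  expect_identical(optimal_chi(ca_pp, 1, kin, 146)$chi,
                   optimal_chi(ca_pp, 10, kin, 146)$chi)
  expect_error(optimal_chi(ca_pp, 1000, kin, -2), "beta_cost")
})

test_that("the water-cost ratio is a saturating, monotone function of soil moisture", {
  sw <- seq(0.02, 0.6, by = 0.02)
  b <- mwue_beta(sw, zeta0 = 0.12)
  expect_true(all(diff(b) > 0))
  expect_lt(abs(b[length(b)] - fx_cfg$mwue$beta0) / fx_cfg$mwue$beta0, 0.01)
  expect_error(mwue_beta(0.3, zeta0 = -1), "zeta0")
  expect_error(mwue_beta(1.4, zeta0 = 0.12), "swc")
})

test_that("GPP is monotone non-decreasing along a soil-moisture sweep", {
  site <- fx_site("S10")
  m <- fx_clim12("S10")[7, ]
  sw <- seq(0.05, 0.45, by = 0.05)
  g <- vapply(sw, function(s) {
    mm <- m; mm$swc <- s
    monthly_gpp(mm, site, fx_cfg)$gpp
  }, numeric(1))
  expect_true(all(diff(g) >= 0))
})

test_that("Fick inversion: g recovers A and degenerate gradients error", {
  set.seed(3)
  for (k in 1:20) {
    a <- runif(1, 0.1, 30); ca_pp <- runif(1, 30, 70)
    ci <- ca_pp * runif(1, 0.3, 0.95)
    g <- stomatal_g(a, ca_pp, ci)
    expect_lt(abs(g * (ca_pp - ci) - a) / a, 1e-12)
  }
  expect_identical(stomatal_g(0, 40, 30), 0)
  expect_equal(stomatal_g(10, 40, 30), 2 * stomatal_g(5, 40, 30))
  expect_error(stomatal_g(5, 30, 31), "gradient")
})
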
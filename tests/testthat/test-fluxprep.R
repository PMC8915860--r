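test_that("quality filtering masks failing rows for drivers and GPP but conserves records", {
  rec <- make_month_records(2001, 6, n_days = 5, n_day_slots = 20, n_bad = 3)
  out <- qc_filter(rec)
  expect_identical(nrow(out), nrow(rec))
  expect_identical(sum(!out$qc_pass), 3L)
  expect_true(all(is.na(out$VPD_F[!out$qc_pass])))
  expect_true(all(is.na(out$GPP_NT_VUT_MEAN[!out$qc_pass])))
  expect_true(all(grepl("VPD_F", out$qc_reason[!out$qc_pass])))
  clean <- qc_filter(make_month_records(2001, 6, 5, 20))
  expect_true(all(clean$qc_pass))
  expect_false(anyNA(clean$VPD_F))
  bad <- rec; bad$TA_F_QC[1] <- 7L
  expect_error(qc_filter(bad), "unknown quality flag")
})

test_that("two-stage monthly daytime means handle unbalanced gaps correctly", {
  rec <- make_month_records(2001, 7, n_days = 2, n_day_slots = 2)
  # slot values: day 1 has 10 and 20, day 2 only the first slot (30);
  # second slot of day 2 is masked through a bad flag
  day_idx <- which(rec$NIGHT == 0)
  rec$TA_F[day_idx] <- c(10, 20, 40, 999)
  rec$TA_F_QC[day_idx[4]] <- 2L
  mq <- monthly_daytime_mean(qc_filter(rec))
  # two-stage: slot means (25, 20) -> 22.5; the naive pooled mean of the
  # three surviving records would be 23.33
  expect_equal(mq$TA_F, mean(c(mean(c(10, 40)), 20)))
  expect_false(isTRUE(all.equal(mq$TA_F, mean(c(10, 20, 40)))))
  # constant series: mean equals the constant
  rec2 <- make_month_records(2001, 8, 3, 10)
  mq2 <- monthly_daytime_mean(qc_filter(rec2))
  expect_equal(mq2$TA_F, 15)
  # an all-night month is flagged empty
  rec3 <- make_month_records(2001, 9, 2, 10)
  rec3$NIGHT <- 1L
  rec3$SW_IN_F <- 0
  mq3 <- monthly_daytime_mean(qc_filter(rec3))
  expect_true(mq3$empty)
})

test_that("the reference GPP is the mean of the four partitioning variants", {
  mq <- data.frame(GPP_NT_VUT_MEAN = 2, GPP_DT_VUT_MEAN = 4,
                   GPP_NT_CUT_MEAN = 6, GPP_DT_CUT_MEAN = 8)
  expect_equal(reference_gpp(mq)$gpp_ref, 5)
  mq2 <- data.frame(GPP_NT_VUT_MEAN = 3, GPP_DT_VUT_MEAN = 3,
                    GPP_NT_CUT_MEAN = 3, GPP_DT_CUT_MEAN = 3)
  expect_equal(reference_gpp(mq2)$gpp_ref, 3)
})

test_that("month exclusion thresholds are exact at the boundaries", {
  mq <- data.frame(year = 2001, month = 1:4,
                   good_frac = c(0.49, 0.50, 1, 1),
                   gpp_ref = c(50, 50, -0.1, 0),
                   empty = FALSE)
  out <- exclude_months(mq)
  expect_identical(out$retained, c(FALSE, TRUE, FALSE, TRUE))
  expect_identical(out$reason, c("low_quality", "", "negative_gpp", ""))
})

test_that("anomalies are zero-mean per site and averaged across the network", {
  ann <- data.frame(site = rep(c("A", "B"), each = 4),
                    year = rep(2001:2004, 2),
                    value = c(10, 12, 14, 16, 7, 7, 7, 7))
  an <- anomalies(ann)
  per_site <- tapply(an$site_anomalies$anomaly, an$site_anomalies$site, sum)
  expect_equal(as.numeric(per_site), c(0, 0), tolerance = 1e-12)
  expect_equal(an$network$anomaly, c(-1.5, -0.5, 0.5, 1.5))
  expect_identical(an$network$n_sites, rep(2L, 4))
})

test_that("the preprocessing chain is idempotent and the no-filter pathway retains more", {
  sc <- synth_config("fixture", years = 2001)
  rec <- gen_flux_fixture(sc, 51, corrupt_months = c("4" = 0.7))
  a <- fluxprep_monthly(rec)
  b <- fluxprep_monthly(rec)
  expect_identical(a, b)
  nf <- fluxprep_monthly(rec, filter = FALSE)
  expect_gt(sum(nf$retained), sum(a$retained))
  # record-count conservation: every month accounted for with a reason code
  expect_identical(nrow(a), 12L)
  expect_true(all(a$reason[!a$retained] != ""))
})
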
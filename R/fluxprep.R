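## FLUXNET2015-style preprocessing. Column conventions follow the FULLSET
## product: TIMESTAMP_START (YYYYMMDDHHMM), TA_F (degC), SW_IN_F (W m-2),
## VPD_F (hPa), PA_F (kPa), SWC_F_MDS_1 (%), NIGHT (0/1), quality flags
## *_QC in {0,1,2,3} (0 measured, 1 good gap-fill, 2/3 poorer), and the four
## GPP partitioning variants (umol CO2 m-2 s-1).

.flux_qc_vars <- c("TA_F", "SW_IN_F", "VPD_F")
.flux_gpp_vars <- c("GPP_NT_VUT_MEAN", "GPP_DT_VUT_MEAN",
                    "GPP_NT_CUT_MEAN", "GPP_DT_CUT_MEAN")

#' Read a FLUXNET-style delimited file
#'
#' Plain CSV reader that converts the -9999 missing-value convention to NA.
#'
#' @param path file path.
#' @return data.frame of records.
#' @export
read_fluxnet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) { x[x <= -9990] <- NA; x })
  df
}

#' Quality filtering of half-hourly/hourly records
#'
#' Keeps only timestamps where air temperature, shortwave radiation and VPD
#' are measured or gap-filled with good quality (flag 0 or 1); failing rows
#' are masked (set to NA) for those drivers and for all GPP variants, but
#' never dropped, so record counts are conserved at every stage. Soil water
#' content carries no quality flag in this step and is left untouched.
#'
#' @param records data.frame of records with `*_QC` columns for the filter
#'   variables.
#' @param qc_vars variables whose flags are checked (default TA_F, SW_IN_F,
#'   VPD_F).
#' @param max_qf largest acceptable flag (default 1).
#' @param apply if FALSE, only annotate `qc_pass`/`qc_reason` without
#'   masking (the no-filter comparison pathway).
#' @return `records` with added logical `qc_pass` and character `qc_reason`.
#' @export
qc_filter <- function(records, qc_vars = .flux_qc_vars, max_qf = 1,
                      apply = TRUE) {
  flags <- paste0(qc_vars, "_QC")
  miss <- setdiff(flags, names(records))
  if (length(miss)) stop("qc_filter: missing flag columns: ", paste(miss, collapse = ", "))
  for (fc in flags) {
    bad <- !is.na(records[[fc]]) & !(records[[fc]] %in% 0:3)
    if (any(bad)) stop("qc_filter: unknown quality flag value in ", fc)
  }
  fail <- matrix(FALSE, nrow(records), length(qc_vars))
  for (j in seq_along(qc_vars)) {
    f <- records[[flags[j]]]
    fail[, j] <- is.na(f) | f > max_qf
  }
  records$qc_pass <- rowSums(fail) == 0
  records$qc_reason <- base::apply(fail, 1L, function(r) {
    if (!any(r)) "" else paste0("qc_fail:", paste(qc_vars[r], collapse = "+"))
  })
  if (apply) {
    maskable <- intersect(c(qc_vars, .flux_gpp_vars), names(records))
    for (v in maskable) records[[v]][!records$qc_pass] <- NA
  }
  records
}

.ts_parts <- function(records) {
  ts <- as.character(records$TIMESTAMP_START)
  list(year = as.integer(substr(ts, 1, 4)),
       month = as.integer(substr(ts, 5, 6)),
       tod = substr(ts, 9, 12))
}

#' Monthly daytime means of drivers and monthly GPP
#'
#' Two-stage aggregation: first the monthly mean of each variable at a given
#' half-hour/hour of day, then the average across daytime slots (robust to
#' unevenly distributed gaps). A slot is daytime when the nighttime flag is
#' 0 and shortwave radiation exceeds 0 W m-2 for the majority of its
#' records. GPP variants are aggregated over all slots and converted to
#' monthly totals (gC m-2 mo-1). The good-quality fraction counts daytime
#' records passing [qc_filter()].
#'
#' @param records output of [qc_filter()] (or raw records; rows lacking
#'   `qc_pass` count as good).
#' @param vars driver columns to average (default TA_F, SW_IN_F, VPD_F,
#'   PA_F, SWC_F_MDS_1).
#' @return data.frame, one row per (year, month): daytime driver means,
#'   monthly GPP totals per variant, `good_frac`, `n_daytime`, `dayfrac`
#'   (fraction of records that are daytime) and `empty` (no daytime
#'   records).
#' @export
monthly_daytime_mean <- function(records,
                                 vars = c("TA_F", "SW_IN_F", "VPD_F", "PA_F",
                                          "SWC_F_MDS_1")) {
  tp <- .ts_parts(records)
  if (is.null(records$qc_pass)) records$qc_pass <- TRUE
  # nighttime flag is authoritative; the SW > 0 cross-check applies only
  # where radiation survived the quality mask
  daytime <- records$NIGHT == 0 &
    (is.na(records$SW_IN_F) | records$SW_IN_F > 0)
  ym <- paste(tp$year, sprintf("%02d", tp$month), sep = "-")
  # records per timestamp slot
  step_s <- .cadence_seconds(records)
  out <- lapply(split(seq_len(nrow(records)), ym), function(idx) {
    r <- records[idx, ]
    dt <- daytime[idx]
    tod <- tp$tod[idx]
    slot_day <- tapply(dt, tod, mean) > 0.5
    day_slots <- names(slot_day)[slot_day]
    two_stage <- function(v, slots = day_slots) {
      pt <- tapply(v, tod, mean, na.rm = TRUE)
      mean(pt[names(pt) %in% slots], na.rm = TRUE)
    }
    drv <- vapply(vars, function(v) two_stage(r[[v]]), numeric(1))
    gpp <- vapply(intersect(.flux_gpp_vars, names(r)), function(v) {
      two_stage(r[[v]], slots = unique(tod)) * length(unique(tod)) *
        step_s * mean(table(tod)) * 12.011e-6
    }, numeric(1))
    c(year = tp$year[idx][1], month = tp$month[idx][1], drv, gpp,
      good_frac = if (any(dt)) mean(r$qc_pass[dt]) else NA_real_,
      n_daytime = sum(dt), dayfrac = mean(dt))
  })
  out <- as.data.frame(do.call(rbind, out))
  rownames(out) <- NULL
  out$empty <- out$n_daytime == 0
  out[order(out$year, out$month), ]
}

.cadence_seconds <- function(records) {
  ts <- as.character(records$TIMESTAMP_START)
  mins <- as.integer(substr(ts, 11, 12)) + 60 * as.integer(substr(ts, 9, 10))
  u <- sort(unique(mins))
  if (length(u) < 2) return(1800)
  min(diff(u)) * 60
}

#' Reference EC-inferred GPP
#'
#' The mean of the four partitioning/friction-velocity variants
#' (NT/DT x VUT/CUT) is the main reference; the individual variants are
#' retained for uncertainty envelopes.
#'
#' @param monthqc output of [monthly_daytime_mean()].
#' @return `monthqc` with an added `gpp_ref` column (gC m-2 mo-1).
#' @export
reference_gpp <- function(monthqc) {
  vars <- intersect(.flux_gpp_vars, names(monthqc))
  if (!length(vars)) stop("reference_gpp: no GPP variant columns present")
  monthqc$gpp_ref <- rowMeans(monthqc[vars], na.rm = FALSE)
  monthqc
}

#' Exclude low-quality months
#'
#' Drops (flags, never deletes) monthly averages with less than the minimum
#' fraction of good-quality daytime timestamps, or negative reference GPP,
#' or no daytime records at all. The boundary is exclusive: exactly 50%
#' good-quality is retained.
#'
#' @param monthqc output of [reference_gpp()].
#' @param min_good_frac threshold fraction (default 0.5).
#' @return `monthqc` with logical `retained` and character `reason`
#'   ("", "no_daytime", "low_quality", "negative_gpp").
#' @export
exclude_months <- function(monthqc, min_good_frac = 0.5) {
  reason <- rep("", nrow(monthqc))
  reason[monthqc$empty | is.na(monthqc$good_frac)] <- "no_daytime"
  low <- reason == "" & monthqc$good_frac < min_good_frac
  reason[low] <- "low_quality"
  neg <- reason == "" & !is.na(monthqc$gpp_ref) & monthqc$gpp_ref < 0
  reason[neg] <- "negative_gpp"
  monthqc$retained <- reason == ""
  monthqc$reason <- reason
  monthqc
}

#' Screen site-years for annual analysis
#'
#' Applies the growing-season gap rules (via [annual_aggregate()]) per site:
#' the growing season is the set of calendar months whose climatological
#' reference GPP exceeds 30 gC m-2 mo-1; a year with exactly one missing
#' growing-season month is backfilled from its low-quality (unfiltered)
#' value; years with more gaps are excluded. Sites qualify with more than
#' `min_years` good years (strict: at least `min_years + 1`).
#'
#' @param monthly data.frame with `site`, `year`, `month`, `gpp` (NA where
#'   excluded/missing) and optionally `gpp_backup` (the no-filter values).
#' @param min_years strict lower bound on qualified years (default 5).
#' @param gs_threshold growing-season threshold (gC m-2 mo-1, default 30).
#' @param max_gap maximum backfillable growing-season gaps (default 1).
#' @return list with `annual` (site, year, gpp, status) and `sites`
#'   (site, n_years, qualified).
#' @export
annual_screen <- function(monthly, min_years = 5, gs_threshold = 30,
                          max_gap = 1) {
  stopifnot(all(c("site", "year", "month", "gpp") %in% names(monthly)))
  pieces <- lapply(split(monthly, monthly$site), function(sm) {
    ann <- annual_aggregate(sm, gap_policy = list(gs_threshold = gs_threshold,
                                                  max_gap = max_gap))
    ann$site <- sm$site[1]
    ann
  })
  annual <- do.call(rbind, pieces)
  rownames(annual) <- NULL
  nyr <- tapply(annual$status != "excluded", annual$site, sum)
  sites <- data.frame(site = names(nyr), n_years = as.integer(nyr),
                      qualified = as.integer(nyr) > min_years)
  list(annual = annual[c("site", "year", "gpp", "status", "n_gs_gaps")],
       sites = sites)
}

#' Annual anomalies and the network-mean series
#'
#' Deviation of each site's annual GPP from its own climatological mean
#' over the study period, then averaged across sites per year.
#'
#' @param annual data.frame with `site`, `year`, `value`.
#' @return list with `site_anomalies` (site, year, anomaly) and `network`
#'   (year, anomaly, n_sites).
#' @export
anomalies <- function(annual) {
  stopifnot(all(c("site", "year", "value") %in% names(annual)))
  ok <- is.finite(annual$value)
  a <- annual[ok, ]
  a$anomaly <- a$value - stats::ave(a$value, a$site)
  netw <- stats::aggregate(a["anomaly"], by = list(year = a$year), FUN = mean)
  netw$n_sites <- as.integer(table(a$year)[as.character(netw$year)])
  list(site_anomalies = a[c("site", "year", "anomaly")], network = netw)
}

#' Full monthly preprocessing chain
#'
#' Convenience wrapper: quality filter, two-stage monthly daytime means,
#' reference GPP and month exclusion. With `filter = FALSE` the quality
#' masking and exclusion are skipped (every month retained), which yields
#' the strictly larger record set used for the no-filter comparison and for
#' backfill values.
#'
#' @param records half-hourly/hourly records.
#' @param filter apply quality filtering and month exclusion (default TRUE).
#' @return MonthQC data.frame (see [exclude_months()]).
#' @export
fluxprep_monthly <- function(records, filter = TRUE) {
  rec <- qc_filter(records, apply = filter)
  mq <- monthly_daytime_mean(rec)
  mq <- reference_gpp(mq)
  if (filter) {
    exclude_months(mq)
  } else {
    mq$retained <- !mq$empty
    mq$reason <- ifelse(mq$empty, "no_daytime", "")
    mq
  }
}

#' Convert preprocessed months to model forcing
#'
#' Maps FLUXNET units to the model's (VPD hPa to Pa then to specific
#' humidity, PA kPa to Pa, SWC percent to fraction) and joins externally
#' supplied CO2 and LAI monthly series.
#'
#' @param monthqc retained months from [fluxprep_monthly()].
#' @param ca monthly CO2 (ppm), recycled or matched by (year, month) if a
#'   data.frame with `year`, `month`, `ca`.
#' @param lai monthly LAI, same conventions.
#' @param ndays days per month (default by calendar month).
#' @return forcing table for [monthly_gpp()] with `gpp_ref` carried along.
#' @export
fluxprep_to_meteo <- function(monthqc, ca, lai,
                              ndays = c(31, 28.25, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)) {
  m <- monthqc
  p <- m$PA_F * 1000
  ta <- m$TA_F
  qa <- vpd_to_q(m$VPD_F * 100, ta, p)
  lookup <- function(x) {
    if (is.data.frame(x)) {
      key <- paste(m$year, m$month)
      x[[3]][match(key, paste(x$year, x$month))]
    } else rep_len(x, nrow(m))
  }
  met <- data.frame(year = m$year, month = m$month, ta = ta, swin = m$SW_IN_F,
                    p = p, qa = qa, swc = m$SWC_F_MDS_1 / 100,
                    ca = lookup(ca), lai = lookup(lai),
                    dayfrac = m$dayfrac, ndays = ndays[m$month],
                    gpp_ref = m$gpp_ref)
  met
}
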
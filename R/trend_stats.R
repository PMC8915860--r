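## Nonparametric trend machinery: Mann-Kendall test with tie-corrected
## variance, Theil-Sen (median of pairwise slopes) estimate, optional
## trend-free prewhitening, site-year resampling, and the detrended-SD
## definition of interannual variability.

#' Mann-Kendall trend test with Theil-Sen slope
#'
#' S statistic with tie-corrected variance and the normal approximation
#' (continuity corrected); slope is the median of all pairwise slopes,
#' intercept the median of `y - slope * x`. Optional trend-free prewhitening
#' removes lag-1 autocorrelation from the detrended series before testing,
#' as in the common field implementations.
#'
#' @param y numeric series (>= 4 non-missing points).
#' @param x time coordinate (default `seq_along(y)`).
#' @param prewhiten logical; apply trend-free prewhitening (default FALSE).
#' @return list with `slope` (per unit `x`), `intercept`, `p_value`, `s`,
#'   `n`, `method`.
#' @export
#' @examples
#' mann_kendall_sen(c(1, 2, 3, 4, 5, 6))$slope  # exactly 1
mann_kendall_sen <- function(y, x = seq_along(y), prewhiten = FALSE) {
  ok <- is.finite(y) & is.finite(x)
  y <- y[ok]; x <- x[ok]
  n <- length(y)
  if (n < 4) stop("mann_kendall_sen: need at least 4 points")
  method <- "mann_kendall_sen"
  if (prewhiten) {
    b <- .sen_slope(y, x)
    detr <- y - b * x
    r1 <- stats::cor(detr[-1], detr[-n])
    if (is.finite(r1) && abs(r1) > 2 / sqrt(n)) {
      w <- detr[-1] - r1 * detr[-n]
      y <- w + b * x[-1]
      x <- x[-1]
      n <- length(y)
      method <- "mann_kendall_sen_tfpw"
    }
  }
  s <- 0
  for (i in seq_len(n - 1)) {
    s <- s + sum(sign(y[(i + 1):n] - y[i]))
  }
  ties <- table(y)
  tie_term <- sum(ties * (ties - 1) * (2 * ties + 5))
  v <- (n * (n - 1) * (2 * n + 5) - tie_term) / 18
  if (v <= 0) {
    p <- 1
  } else {
    z <- (s - sign(s)) / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
  }
  slope <- .sen_slope(y, x)
  list(slope = slope, intercept = stats::median(y - slope * x),
       p_value = p, s = s, n = n, method = method)
}

.sen_slope <- function(y, x) {
  n <- length(y)
  num <- outer(y, y, "-")[lower.tri(diag(n))]
  den <- outer(x, x, "-")[lower.tri(diag(n))]
  sl <- num / den
  sl <- sl[is.finite(sl)]
  if (!length(sl)) return(0)
  stats::median(sl)
}

#' Interannual variability as detrended standard deviation
#'
#' One standard deviation of the series after removing its long-term trend
#' (Theil-Sen line by default, ordinary least squares optionally).
#'
#' @param y annual series.
#' @param x time coordinate (default `seq_along(y)`).
#' @param detrend "sen" or "ols".
#' @return scalar IAV in the units of `y`.
#' @export
iav <- function(y, x = seq_along(y), detrend = c("sen", "ols")) {
  detrend <- match.arg(detrend)
  ok <- is.finite(y) & is.finite(x)
  y <- y[ok]; x <- x[ok]
  if (length(y) < 3) return(NA_real_)
  res <- if (detrend == "sen") {
    b <- .sen_slope(y, x)
    y - b * x - stats::median(y - b * x)
  } else {
    stats::residuals(stats::lm(y ~ x))
  }
  stats::sd(res)
}

#' Trend uncertainty by resampling of site-years
#'
#' Repeatedly keeps a fraction (default 50%, without replacement, rounded
#' up) of each site's years, recomputes the network trend, and summarizes
#' the draw distribution. The network trend of a draw is, by default, the
#' Theil-Sen slope of the cross-site mean annual anomaly series (each site's
#' anomaly taken about its own resampled mean); alternatively the mean of
#' per-site trends. Deterministic under a fixed seed; no draw mixes years
#' across sites.
#'
#' @param df data.frame with columns `site`, `year`, `value`.
#' @param frac fraction of each site's years kept per draw.
#' @param n_draws number of draws (default 2000; published analyses of this
#'   kind use up to 2e5, available here by argument).
#' @param seed integer RNG seed (mandatory).
#' @param network_stat "mean_anomaly" or "mean_site_trend".
#' @return list with `draws` (numeric vector), `median`, `iqr` (2-vector),
#'   `mean`, `n_draws`, `n_skipped_site_draws`.
#' @export
resample_trends <- function(df, frac = 0.5, n_draws = 2000, seed,
                            network_stat = c("mean_anomaly", "mean_site_trend")) {
  network_stat <- match.arg(network_stat)
  stopifnot(all(c("site", "year", "value") %in% names(df)))
  if (missing(seed)) stop("resample_trends: `seed` is mandatory")
  set.seed(seed)
  sites <- split(df[c("year", "value")], df$site)
  sites <- lapply(sites, function(s) {
    s <- s[is.finite(s$value), ]
    # anomaly about the site's full study-period mean, fixed across draws
    s$anom <- s$value - mean(s$value)
    s
  })
  draws <- numeric(n_draws)
  skipped <- 0L
  for (k in seq_len(n_draws)) {
    pieces <- lapply(sites, function(s) {
      m <- ceiling(frac * nrow(s))
      if (m < 2) { return(NULL) }
      s[sample.int(nrow(s), m), ]
    })
    nulls <- sum(vapply(pieces, is.null, logical(1)))
    skipped <- skipped + nulls
    pieces <- pieces[!vapply(pieces, is.null, logical(1))]
    if (network_stat == "mean_anomaly") {
      anom <- do.call(rbind, pieces)
      netw <- tapply(anom$anom, anom$year, mean)
      yrs <- as.numeric(names(netw))
      draws[k] <- if (length(netw) >= 4) {
        mann_kendall_sen(as.numeric(netw), yrs)$slope
      } else NA_real_
    } else {
      tr <- vapply(pieces, function(s) {
        if (nrow(s) >= 4) mann_kendall_sen(s$value, s$year)$slope else NA_real_
      }, numeric(1))
      draws[k] <- mean(tr, na.rm = TRUE)
    }
  }
  dd <- draws[is.finite(draws)]
  list(draws = draws, median = stats::median(dd),
       iqr = stats::quantile(dd, c(0.25, 0.75), names = FALSE),
       mean = mean(dd), n_draws = n_draws, n_skipped_site_draws = skipped)
}
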
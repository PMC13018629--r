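#' Replicated measurement series
#'
#' Long-format container for replicated OD600 or CFU measurements along a
#' growth curve. CFU data with a biological x technical hierarchy should
#' first be collapsed with [collapse_technical()] so that the smoother
#' weights biological replicates equally.
#'
#' @param time_h measurement times, hours.
#' @param value positive measurements (OD600 or CFU/ml).
#' @param replicate replicate identifier (recycled if scalar).
#' @param kind `"od"`, `"cfu"` or `"ratio"`.
#' @return object of class `replicated_series` (a data.frame).
#' @export
replicated_series <- function(time_h, value, replicate = 1,
                              kind = c("od", "cfu", "ratio")) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(time_h), is.numeric(value),
            length(time_h) == length(value), all(value > 0))
  out <- data.frame(time_h = time_h, replicate = rep_len(replicate, length(time_h)),
                    value = value)
  structure(out, kind = kind, class = c("replicated_series", "data.frame"))
}

#' Collapse technical replicates onto their biological replicate
#'
#' Averages the technical replicates within each `(time_h, bio_rep)` cell,
#' so each biological replicate contributes one value per time point
#' regardless of how many technical replicates it had.
#'
#' @param df data.frame with columns `time_h`, `bio_rep`, `tech_rep` and a
#'   value column (`cfu_per_ml` or `value`).
#' @param value_col name of the value column.
#' @return data.frame with `time_h`, `bio_rep`, `value`.
#' @export
collapse_technical <- function(df, value_col = "cfu_per_ml") {
  stopifnot(all(c("time_h", "bio_rep", value_col) %in% names(df)))
  agg <- stats::aggregate(df[[value_col]],
                          by = list(time_h = df$time_h, bio_rep = df$bio_rep),
                          FUN = mean)
  names(agg)[3] <- "value"
  agg[order(agg$time_h, agg$bio_rep), , drop = FALSE]
}

#' Smoothed trend with a pointwise 95% confidence band
#'
#' Nonparametric regression of log-measurements on time (penalised
#' regression spline, REML smoothness selection), evaluated on a grid and
#' back-transformed. The band is the back-transformed pointwise 95%
#' interval of the fitted log-trend; the returned half-width is half its
#' width on the original scale.
#'
#' @param series a [replicated_series()] (or data.frame with `time_h`,
#'   `value`); needs at least 4 distinct time points.
#' @param grid evaluation times, hours (defaults to 101 points over the
#'   data range).
#' @param seed kept for interface stability; the smoother itself is
#'   deterministic.
#' @return object of class `trend_band`: data.frame with `time_h`, `mean`,
#'   `halfwidth`, and a `kind` attribute.
#' @export
smooth_trend <- function(series, grid = NULL, seed = 1) {
  stopifnot(is.data.frame(series),
            all(c("time_h", "value") %in% names(series)),
            all(series$value > 0))
  n_t <- length(unique(series$time_h))
  if (n_t < 4) stop("need at least 4 distinct time points to smooth a trend")
  if (is.null(grid))
    grid <- seq(min(series$time_h), max(series$time_h), length.out = 101)
  kk <- min(10, n_t - 1)
  dat <- data.frame(t = series$time_h, y = log(series$value))
  if (stats::sd(dat$y) < 1e-10) {   # constant series: degenerate smooth
    out <- data.frame(time_h = grid, mean = exp(mean(dat$y)), halfwidth = 0)
    kind <- attr(series, "kind")
    return(structure(out, kind = if (is.null(kind)) "od" else kind,
                     class = c("trend_band", "data.frame")))
  }
  fit <- mgcv::gam(y ~ s(t, k = kk), data = dat, method = "REML")
  pr <- mgcv::predict.gam(fit, newdata = data.frame(t = grid), se.fit = TRUE)
  lo <- exp(pr$fit - 1.96 * pr$se.fit)
  hi <- exp(pr$fit + 1.96 * pr$se.fit)
  out <- data.frame(time_h = grid, mean = exp(pr$fit), halfwidth = (hi - lo) / 2)
  kind <- attr(series, "kind")
  structure(out, kind = if (is.null(kind)) "od" else kind,
            class = c("trend_band", "data.frame"))
}

#' @export
print.trend_band <- function(x, ...) {
  cat(sprintf("Smoothed %s trend: %d grid points on [%g, %g] h\n",
              attr(x, "kind"), nrow(x), min(x$time_h), max(x$time_h)))
  invisible(x)
}

#' Ratio of two trends with first-order uncertainty propagation
#'
#' For trends `x` (numerator, e.g. OD600) and `y` (denominator, e.g. CFU)
#' sharing a grid, the ratio is `z = x/y` and the propagated half-width is
#' the first-order absolute sum
#' `dz = |dx / y| + |x dy / y^2|`,
#' the standard (conservative) propagation for 95% half-widths.
#'
#' @param od_trend,cfu_trend `trend_band` objects on identical grids.
#' @return `trend_band` of kind `"ratio"`.
#' @export
ratio_with_uncertainty <- function(od_trend, cfu_trend) {
  stopifnot(inherits(od_trend, "trend_band"), inherits(cfu_trend, "trend_band"))
  if (!isTRUE(all.equal(od_trend$time_h, cfu_trend$time_h)))
    stop("trends must share the same time grid")
  x <- od_trend$mean; dx <- od_trend$halfwidth
  y <- cfu_trend$mean; dy <- cfu_trend$halfwidth
  out <- data.frame(time_h = od_trend$time_h,
                    mean = x / y,
                    halfwidth = abs(dx / y) + abs(x * dy / y^2))
  structure(out, kind = "ratio", class = c("trend_band", "data.frame"))
}

#' Locate the peak of a trend
#'
#' Argmax of the smoothed mean trajectory, its value, and the fold increase
#' relative to the first grid point. A maximum attained at the grid
#' boundary (including flat trends) is flagged as no interior peak.
#'
#' @param trend a `trend_band`.
#' @return list with `t_peak_h`, `peak_value`, `fold_increase_vs_t0` and
#'   logical `interior`.
#' @export
peak_locate <- function(trend) {
  stopifnot(inherits(trend, "trend_band"), nrow(trend) >= 3)
  i <- which.max(trend$mean)
  interior <- i > 1 && i < nrow(trend) &&
    trend$mean[i] > trend$mean[1] && trend$mean[i] > trend$mean[nrow(trend)]
  list(t_peak_h = trend$time_h[i],
       peak_value = trend$mean[i],
       fold_increase_vs_t0 = trend$mean[i] / trend$mean[1],
       interior = interior)
}
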
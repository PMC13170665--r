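# Linear trends with significance and the two turning-point detectors
# (start-year trend scan, continuous segmented regression), plus the
# three-phase partition of the wind record.

#' Ordinary-least-squares linear trend of a series
#'
#' Fits `y ~ year` over the requested period and reports the slope per
#' decade (slope per year x 10), the two-sided t-test p-value on the slope,
#' and optionally the slope as percent of a baseline mean per decade (the
#' convention used for wind: trend / baseline mean x 100).
#'
#' @param values Numeric series.
#' @param years Numeric time axis (same length).
#' @param period Optional `c(first, last)` restriction (inclusive).
#' @param baseline_mean Denominator for the percent-per-decade convention;
#'   defaults to the mean of the series over the period (`NA` disables).
#' @param alpha Significance level for the `significant` flag (default
#'   0.05).
#' @return Object of class `wue_trend`: `slope` (per year),
#'   `slope_per_decade`, `intercept`, `p_value`, `significant`,
#'   `percent_per_decade`, `period`, `n`.
#' @export
#' @examples
#' tr <- linear_trend(3.35 - 0.0072 * (0:27), 1983:2010)
#' tr$slope_per_decade
linear_trend <- function(values, years, period = NULL, baseline_mean = NULL,
                         alpha = 0.05) {
  stopifnot(length(values) == length(years))
  if (!is.null(period)) {
    sel <- years >= period[1] & years <= period[2]
    values <- values[sel]
    years <- years[sel]
  }
  ok <- is.finite(values) & is.finite(years)
  values <- values[ok]
  years <- years[ok]
  n <- length(values)
  if (n < 3L) stop("need at least 3 points to fit a trend", call. = FALSE)
  tc <- years - mean(years)
  sxx <- sum(tc^2)
  slope <- sum(tc * (values - mean(values))) / sxx
  intercept <- mean(values) - slope * mean(years)
  resid <- values - (intercept + slope * years)
  rss <- sum(resid^2)
  se <- sqrt(rss / (n - 2) / sxx)
  p <- if (se > 0) {
    2 * stats::pt(abs(slope / se), df = n - 2, lower.tail = FALSE)
  } else if (abs(slope) > 0) 0 else NA_real_
  bm <- baseline_mean %||% mean(values)
  structure(
    list(slope = slope, slope_per_decade = slope * 10,
         intercept = intercept, p_value = p,
         significant = isTRUE(p < alpha),
         percent_per_decade = if (is.finite(bm) && bm != 0) {
           100 * slope * 10 / bm
         } else NA_real_,
         period = range(years), n = n),
    class = "wue_trend"
  )
}

#' @export
print.wue_trend <- function(x, ...) {
  cat(sprintf("<wue_trend> %.0f-%.0f: %+.4g per decade (p = %.3g%s)\n",
              x$period[1], x$period[2], x$slope_per_decade, x$p_value,
              if (isTRUE(x$significant)) ", significant" else ""))
  invisible(x)
}

#' Per-pixel trend maps
#'
#' OLS slope (per year) and p-value at every pixel of a gridded field over a
#' period; pixels with fewer than 3 finite values are missing.
#'
#' @param field A [gridded_field()].
#' @param period Optional `c(first, last)` year restriction.
#' @return List with matrices `slope`, `p_value` and the axes.
#' @export
trend_grid <- function(field, period = NULL) {
  yrs <- field$time
  sel <- if (is.null(period)) rep(TRUE, length(yrs)) else
    (yrs >= period[1] & yrs <= period[2])
  m <- pixel_matrix(field)[sel, , drop = FALSE]
  t <- yrs[sel]
  d <- dim(field$values)
  slope <- matrix(NA_real_, d[2], d[3])
  pval <- matrix(NA_real_, d[2], d[3])
  for (px in seq_len(ncol(m))) {
    y <- m[, px]
    ok <- is.finite(y)
    if (sum(ok) < 3L) next
    tr <- linear_trend(y[ok], t[ok])
    slope[px] <- tr$slope
    pval[px] <- tr$p_value
  }
  list(slope = slope, p_value = pval, lat = field$lat, lon = field$lon,
       period = range(t))
}

#' Start-year trend scan for a turning point
#'
#' Fits one OLS trend per candidate start year (end year fixed) and returns
#' the start year whose trend is most negative — the likely onset of the
#' next decline phase. Ties (within a small numeric tolerance, relevant for
#' noise-free piecewise-linear input where all post-break starts give the
#' identical slope) are broken to the earliest year.
#'
#' @param values,years Series and its time axis; must cover
#'   `[min(start_range), end]`.
#' @param start_range Candidate start years, default `c(2010, 2080)`.
#' @param end Fixed end year, default 2100.
#' @param tie_tol Absolute slope tolerance treated as a tie (default 1e-12).
#' @return Object of class `turning_point` (`method = "scan"`, `year`,
#'   `diagnostics`: per-candidate slopes).
#' @export
scan_turning_point <- function(values, years, start_range = c(2010, 2080),
                               end = 2100, tie_tol = 1e-12) {
  starts <- seq(start_range[1], start_range[2])
  if (min(years) > starts[1] || max(years) < end) {
    stop("series does not cover the scan window", call. = FALSE)
  }
  slopes <- vapply(starts, function(s0) {
    sel <- years >= s0 & years <= end
    ols_slope(values[sel], years[sel])
  }, numeric(1))
  best <- min(slopes, na.rm = TRUE)
  year <- starts[which(slopes <= best + tie_tol)[1]]
  structure(list(method = "scan", year = year,
                 diagnostics = data.frame(start = starts, slope = slopes)),
            class = "turning_point")
}

#' Segmented (piecewise-linear) regression turning point
#'
#' Exhaustive search over candidate breakpoint years: at each candidate a
#' two-segment linear model is fitted by least squares and the
#' residual-sum-of-squares-minimizing year is returned. The default model is
#' continuous at the break (slope change via a hinge term); a discontinuous
#' variant (independent fits either side) is available for sensitivity
#' checks. No heuristic shortcuts: every admissible candidate is evaluated.
#'
#' @param values,years Series and time axis.
#' @param min_segment Minimum points per segment (default 5, guards against
#'   endpoint artifacts).
#' @param continuous Continuous-at-the-break model? (default `TRUE`).
#' @return Object of class `turning_point` (`method = "segmented"`, `year`,
#'   `diagnostics`: per-candidate RSS).
#' @export
segmented_turning_point <- function(values, years, min_segment = 5L,
                                    continuous = TRUE) {
  ok <- is.finite(values) & is.finite(years)
  values <- values[ok]
  years <- years[ok]
  n <- length(values)
  if (n < 2L * min_segment) {
    stop(sprintf("series too short for segmented regression (need >= %d points)",
                 2L * min_segment), call. = FALSE)
  }
  cand <- years[seq(min_segment, n - min_segment)]
  rss <- vapply(cand, function(k) {
    if (continuous) {
      X <- cbind(1, years, pmax(years - k, 0))
      sum(stats::lm.fit(X, values)$residuals^2)
    } else {
      left <- years <= k
      f1 <- stats::lm.fit(cbind(1, years[left]), values[left])
      f2 <- stats::lm.fit(cbind(1, years[!left]), values[!left])
      sum(f1$residuals^2) + sum(f2$residuals^2)
    }
  }, numeric(1))
  best <- min(rss)
  year <- cand[which(rss <= best + 1e-12)[1]]
  structure(list(method = "segmented", year = year,
                 diagnostics = data.frame(year = cand, rss = rss)),
            class = "turning_point")
}

#' @export
print.turning_point <- function(x, ...) {
  cat(sprintf("<turning_point> %s detector: %d\n", x$method, x$year))
  invisible(x)
}

#' Partition a series into three labelled phases
#'
#' Splits the record at two breakpoint years into non-overlapping,
#' exhaustive phases — `[start, break1]`, `[break1 + 1, break2]`,
#' `[break2 + 1, end]` — and attaches a [linear_trend()] to each. Degenerate
#' phases (fewer than 3 points) are rejected.
#'
#' @param values,years Series and time axis.
#' @param break1,break2 Breakpoint years, `break1 < break2`, interior.
#' @return Named list of three phases (`decline`, `reversal`,
#'   `future_decline`), each with `period` and `trend`.
#' @export
#' @examples
#' yrs <- 1983:2100
#' v <- windwue::wind_trajectory(synthetic_spec(grid_shape = c(2, 2)))
#' partition_phases(v, yrs, 2010, 2028)$reversal$period
partition_phases <- function(values, years, break1, break2) {
  if (!(break1 < break2)) stop("break1 must precede break2", call. = FALSE)
  bounds <- list(decline = c(min(years), break1),
                 reversal = c(break1 + 1, break2),
                 future_decline = c(break2 + 1, max(years)))
  out <- lapply(bounds, function(b) {
    sel <- years >= b[1] & years <= b[2]
    if (sum(sel) < 3L) {
      stop(sprintf("degenerate phase %d-%d (fewer than 3 points)", b[1], b[2]),
           call. = FALSE)
    }
    list(period = b, trend = linear_trend(values[sel], years[sel]))
  })
  out
}
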
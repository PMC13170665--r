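# Specification object for the synthetic-data generator. The defaults ARE
# the study conditions the rest of the package is exercised under: a
# triphasic wind trajectory (decline / recovery / decline, breaks 2010 and
# 2028), seven collinear drivers around linear trend lines, and a WUE field
# that is a known linear function of the drivers.

synthetic_variables <- function() {
  c(regression_drivers(), "sm")
}

#' Default cross-driver correlation matrix
#'
#' Interannual (detrended) correlation structure among the seven regression
#' drivers and soil moisture: a strong wind-pressure anticorrelation (the
#' pressure-gradient force), warm years that are sunnier and drier
#' (tair-vpd, tair-swrad positive; vpd-precip, vpd-sm negative), wet years
#' with moister soil (precip-sm positive), and a mild CO2-temperature
#' coupling on top of their shared trends.
#'
#' @return An 8 x 8 symmetric positive-definite correlation matrix with
#'   dimnames `wind, tair, pressure, precip, swrad, vpd, co2, sm`.
#' @export
default_driver_correlation <- function() {
  v <- synthetic_variables()
  C <- diag(length(v))
  dimnames(C) <- list(v, v)
  set_cor <- function(a, b, r) {
    C[a, b] <<- r
    C[b, a] <<- r
  }
  set_cor("wind", "pressure", -0.60)
  set_cor("tair", "vpd", 0.60)
  set_cor("tair", "swrad", 0.40)
  set_cor("tair", "co2", 0.30)
  set_cor("precip", "sm", 0.60)
  set_cor("precip", "vpd", -0.40)
  set_cor("precip", "swrad", -0.30)
  set_cor("vpd", "sm", -0.40)
  set_cor("vpd", "swrad", 0.30)
  C
}

#' Build a synthetic-experiment specification
#'
#' Collects every knob of the synthetic world: grid size, year range,
#' per-driver climatology (level, interannual SD, linear trend), the
#' triphasic wind trajectory, the true WUE sensitivities, the optional
#' wind/soil-moisture interaction, and the residual noise.
#'
#' Units follow field convention throughout: wind m s-1, temperature deg C,
#' pressure kPa, precipitation mm yr-1, shortwave W m-2, VPD kPa, CO2 ppm,
#' soil moisture m3 m-3, WUE g C kg-1 H2O.
#'
#' @param grid_shape Integer `c(n_lat, n_lon)`.
#' @param years Inclusive integer year range, e.g. `c(1983, 2100)`.
#' @param driver_means,driver_sds Named per-variable level and interannual
#'   SD (all eight of `wind, tair, pressure, precip, swrad, vpd, co2, sm`).
#' @param correlation 8 x 8 symmetric positive semi-definite correlation
#'   matrix of the interannual deviations.
#' @param wind_breakpoints Two calendar years splitting the wind mean
#'   trajectory into three linear segments (strictly increasing, interior).
#' @param wind_segment_slopes Per-segment wind slopes, m s-1 yr-1.
#' @param other_trends Named linear slopes per year for the non-wind
#'   variables (CO2 strictly positive).
#' @param true_beta Named true sensitivity of WUE to each of the seven
#'   regression drivers, in original units.
#' @param interaction_gamma Coefficient on the Wind/SM ratio (0 disables).
#' @param noise_sd Residual SD of WUE, g C kg-1 H2O (>= 0).
#' @param wue_mean Target long-term mean WUE used to place the intercept.
#' @param wind_ar1 AR(1) coefficient of the wind noise (default 0: the
#'   regression model assumes independent residuals).
#' @param rng_seed Integer seed; identical spec + seed gives bit-identical
#'   output.
#' @return An object of class `synthetic_spec`.
#' @export
#' @examples
#' sp <- synthetic_spec(grid_shape = c(4, 4), years = c(1983, 2014))
#' sp$true_beta[["wind"]]
synthetic_spec <- function(grid_shape = c(10, 10),
                           years = c(1983, 2100),
                           driver_means = c(wind = 3.35, tair = 10,
                                            pressure = 90, precip = 450,
                                            swrad = 180, vpd = 0.85,
                                            co2 = 360, sm = 0.20),
                           driver_sds = c(wind = 0.20, tair = 0.60,
                                          pressure = 0.25, precip = 55,
                                          swrad = 7, vpd = 0.08,
                                          co2 = 0.8, sm = 0.025),
                           correlation = default_driver_correlation(),
                           wind_breakpoints = c(2010, 2028),
                           wind_segment_slopes = c(-0.0072, 0.0041, -0.0010),
                           other_trends = c(tair = 0.03, pressure = 0,
                                            precip = 0.5, swrad = 0.08,
                                            vpd = 0.002, co2 = 1.8,
                                            sm = -5e-4),
                           true_beta = c(wind = -0.13, tair = 0.015,
                                         pressure = 0.04, precip = 6e-4,
                                         swrad = 0.003, vpd = -0.55,
                                         co2 = 0.002),
                           interaction_gamma = 0,
                           noise_sd = 0.05,
                           wue_mean = 1.5,
                           wind_ar1 = 0,
                           rng_seed = 42L) {
  vars <- synthetic_variables()
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 2L || any(grid_shape < 1L)) {
    stop("`grid_shape` must be two positive counts", call. = FALSE)
  }
  years <- seq(as.integer(min(years)), as.integer(max(years)))
  if (length(years) < 4L) stop("year range too short", call. = FALSE)

  driver_means <- driver_means[vars]
  driver_sds <- driver_sds[vars]
  if (anyNA(driver_means) || anyNA(driver_sds) || any(driver_sds < 0)) {
    stop("driver_means/driver_sds must cover all eight variables, SDs >= 0",
         call. = FALSE)
  }
  if (!is.matrix(correlation) || !identical(dim(correlation), c(8L, 8L))) {
    stop("`correlation` must be an 8 x 8 matrix", call. = FALSE)
  }
  if (is.null(dimnames(correlation))) dimnames(correlation) <- list(vars, vars)
  correlation <- correlation[vars, vars]
  if (max(abs(correlation - t(correlation))) > 1e-10 ||
      max(abs(diag(correlation) - 1)) > 1e-10) {
    stop("`correlation` must be symmetric with a unit diagonal", call. = FALSE)
  }
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop(sprintf(paste0("`correlation` is not positive semi-definite ",
                        "(smallest eigenvalue %.3g); adjust the off-diagonal ",
                        "entries"), min(ev)), call. = FALSE)
  }

  wind_breakpoints <- as.integer(wind_breakpoints)
  if (length(wind_breakpoints) != 2L ||
      wind_breakpoints[1] >= wind_breakpoints[2] ||
      wind_breakpoints[1] <= min(years) || wind_breakpoints[2] >= max(years)) {
    stop("`wind_breakpoints` must be strictly increasing and interior to the year range",
         call. = FALSE)
  }
  if (length(wind_segment_slopes) != 3L) {
    stop("`wind_segment_slopes` needs one slope per segment (three)",
         call. = FALSE)
  }
  other_trends <- other_trends[setdiff(vars, "wind")]
  if (anyNA(other_trends)) {
    stop("`other_trends` must name every non-wind variable", call. = FALSE)
  }
  if (other_trends[["co2"]] <= 0) {
    stop("the CO2 trend must be strictly positive", call. = FALSE)
  }
  true_beta <- true_beta[regression_drivers()]
  if (anyNA(true_beta)) {
    stop("`true_beta` must name all seven regression drivers", call. = FALSE)
  }
  if (!is.finite(noise_sd) || noise_sd < 0) {
    stop("`noise_sd` must be >= 0", call. = FALSE)
  }
  structure(
    list(grid_shape = grid_shape, years = years,
         driver_means = driver_means, driver_sds = driver_sds,
         correlation = correlation,
         wind_breakpoints = wind_breakpoints,
         wind_segment_slopes = as.numeric(wind_segment_slopes),
         other_trends = other_trends, true_beta = true_beta,
         interaction_gamma = interaction_gamma, noise_sd = noise_sd,
         wue_mean = wue_mean, wind_ar1 = wind_ar1,
         rng_seed = as.integer(rng_seed)),
    class = "synthetic_spec"
  )
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf("<synthetic_spec> %d x %d grid, %d-%d, breaks %d/%d, noise_sd %.3g, seed %d\n",
              x$grid_shape[1], x$grid_shape[2], min(x$years), max(x$years),
              x$wind_breakpoints[1], x$wind_breakpoints[2], x$noise_sd,
              x$rng_seed))
  invisible(x)
}

#' Deterministic triphasic wind mean trajectory
#'
#' Continuous piecewise-linear path with the spec's per-segment slopes
#' (decline / recovery / decline), shifted so its mean over the full period
#' equals the spec's wind level.
#'
#' @param spec A [synthetic_spec()].
#' @return Numeric vector along `spec$years`.
#' @export
wind_trajectory <- function(spec) {
  yrs <- spec$years
  b <- spec$wind_breakpoints
  s <- spec$wind_segment_slopes
  v <- numeric(length(yrs))
  for (i in seq_along(yrs)[-1]) {
    sl <- if (yrs[i] <= b[1]) s[1] else if (yrs[i] <= b[2]) s[2] else s[3]
    v[i] <- v[i - 1] + sl
  }
  v - mean(v) + spec$driver_means[["wind"]]
}

# ny x 8 matrix of deterministic mean trajectories for all variables.
mean_trajectories <- function(spec) {
  yrs <- spec$years
  vars <- synthetic_variables()
  out <- matrix(NA_real_, length(yrs), length(vars),
                dimnames = list(NULL, vars))
  tc <- yrs - mean(yrs)
  for (v in setdiff(vars, "wind")) {
    out[, v] <- spec$driver_means[[v]] + spec$other_trends[[v]] * tc
  }
  out[, "wind"] <- wind_trajectory(spec)
  out
}
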
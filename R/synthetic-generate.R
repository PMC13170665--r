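# Seeded generators: gridded drivers, the WUE response, flux-site tables,
# and static disturbance mask layers, plus the ground-truth sidecar.

#' Generate the gridded driver fields
#'
#' Draws annual values for the seven climatic drivers plus soil moisture on
#' the spec's grid. Each pixel's deviations from the deterministic trend
#' lines are multivariate normal with the spec's cross-correlation matrix.
#' CO2 is spatially uniform — one global interannual series shared by every
#' pixel — and the remaining variables are drawn conditionally on it, so the
#' full correlation structure holds at each pixel while CO2 stays
#' rank-deficient as a spatial predictor (as in reality).
#'
#' @param spec A [synthetic_spec()].
#' @return A [driver_set()] with fields
#'   `wind, tair, pressure, precip, swrad, vpd, co2, sm`.
#' @export
#' @examples
#' dr <- generate_drivers(synthetic_spec(grid_shape = c(3, 3),
#'                                       years = c(1983, 2014)))
#' names(dr)
generate_drivers <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  vars <- synthetic_variables()
  yrs <- spec$years
  ny <- length(yrs)
  nlat <- spec$grid_shape[1]
  nlon <- spec$grid_shape[2]
  npix <- nlat * nlon
  mu <- mean_trajectories(spec)

  D <- diag(spec$driver_sds[vars])
  Sigma <- D %*% spec$correlation %*% D
  dimnames(Sigma) <- list(vars, vars)
  ic <- match("co2", vars)
  rest <- setdiff(seq_along(vars), ic)
  s_cc <- Sigma[ic, ic]

  with_seed(spec$rng_seed, {
    # one global CO2 interannual series, shared across pixels
    z_co2 <- if (s_cc > 0) rnorm(ny, 0, sqrt(s_cc)) else numeric(ny)
    if (s_cc > 0) {
      cond_coef <- Sigma[rest, ic] / s_cc
      cond_cov <- Sigma[rest, rest] - tcrossprod(Sigma[rest, ic]) / s_cc
    } else {
      cond_coef <- rep(0, length(rest))
      cond_cov <- Sigma[rest, rest]
    }
    # PSD-safe Cholesky (zero-variance rows allowed)
    ee <- eigen(cond_cov, symmetric = TRUE)
    L <- ee$vectors %*% diag(sqrt(pmax(ee$values, 0)), length(rest))

    eps <- array(0, c(ny, length(vars), npix))
    eps[, ic, ] <- z_co2
    for (px in seq_len(npix)) {
      e <- matrix(rnorm(ny * length(rest)), ny, length(rest)) %*% t(L)
      eps[, rest, px] <- e + outer(z_co2, cond_coef)
    }
    if (spec$wind_ar1 != 0) {
      iw <- match("wind", vars)
      phi <- spec$wind_ar1
      scale <- sqrt(1 - phi^2) # keep the marginal SD at the spec value
      for (px in seq_len(npix)) {
        w <- eps[, iw, px]
        eps[, iw, px] <- as.numeric(stats::filter(w * scale, phi,
                                                  method = "recursive"))
      }
    }
    lat <- seq(20, 60, length.out = nlat)
    lon <- seq(0, 40, length.out = nlon)
    units <- c(wind = "m s-1", tair = "degC", pressure = "kPa",
               precip = "mm yr-1", swrad = "W m-2", vpd = "kPa",
               co2 = "ppm", sm = "m3 m-3")
    fields <- lapply(vars, function(v) {
      iv <- match(v, vars)
      vals <- array(NA_real_, c(ny, nlat, nlon))
      vals[] <- mu[, v] + eps[, iv, ] # recycle over pixels
      gridded_field(vals, yrs, lat, lon, v, units[[v]])
    })
    names(fields) <- vars
    driver_set(fields)
  })
}

# Deterministic (noise-free) part of WUE for a time x driver matrix.
wue_linear_predictor <- function(X, spec, sm = NULL) {
  beta <- spec$true_beta
  lp <- drop(X[, regression_drivers(), drop = FALSE] %*% beta)
  if (spec$interaction_gamma != 0) {
    if (is.null(sm)) stop("soil moisture needed when interaction_gamma != 0",
                          call. = FALSE)
    if (any(sm <= 0, na.rm = TRUE)) {
      stop("soil moisture must be strictly positive when the Wind/SM interaction is enabled",
           call. = FALSE)
    }
    lp <- lp + spec$interaction_gamma * X[, "wind"] / sm
  }
  lp
}

# Intercept placing the long-term mean WUE at spec$wue_mean.
wue_intercept <- function(spec) {
  mu <- mean_trajectories(spec)
  lp <- wue_linear_predictor(mu, spec, sm = mu[, "sm"])
  spec$wue_mean - mean(lp)
}

#' Generate the WUE response field
#'
#' Constructs WUE as a known linear function of the drivers,
#' `WUE = beta0 + sum_j beta_j x_j + gamma * Wind/SM + eps`, with
#' `eps ~ N(0, noise_sd^2)` i.i.d. and seeded independently of the driver
#' stage (so drivers can be regenerated without changing the noise draw).
#'
#' @param drivers A [driver_set()] from [generate_drivers()] with the same
#'   spec.
#' @param spec The [synthetic_spec()].
#' @return A [gridded_field()] named `"wue"` in g C kg-1 H2O.
#' @export
generate_wue <- function(drivers, spec) {
  stopifnot(inherits(drivers, "driver_set"), inherits(spec, "synthetic_spec"))
  ref <- drivers[[1]]
  d <- dim(ref$values)
  npix <- d[2] * d[3]
  X <- vapply(regression_drivers(),
              function(v) as.numeric(pixel_matrix(drivers[[v]])),
              numeric(d[1] * npix))
  smv <- as.numeric(pixel_matrix(drivers[["sm"]]))
  b0 <- wue_intercept(spec)
  det <- b0 + wue_linear_predictor(X, spec, sm = smv)
  noise <- with_seed(derive_seed(spec$rng_seed, "wue_noise"),
                     rnorm(length(det), 0, spec$noise_sd))
  gridded_field(array(det + noise, d), ref$time, ref$lat, ref$lon,
                "wue", "g C kg-1 H2O")
}

#' Calibrate the residual SD to a target coefficient of determination
#'
#' Returns the residual noise SD such that the linear driver signal explains
#' (in expectation) a stated fraction of the total WUE variance at a pixel:
#' `noise_sd = sqrt(var_signal * (1 - R2) / R2)` with `var_signal` the mean
#' per-pixel temporal variance of the noise-free response.
#'
#' @param spec A [synthetic_spec()].
#' @param target_r2 Target R^2 in (0, 1).
#' @param drivers Optional pre-generated [generate_drivers()] output.
#' @return Numeric noise SD (g C kg-1 H2O).
#' @export
calibrate_noise_sd <- function(spec, target_r2, drivers = NULL) {
  stopifnot(target_r2 > 0, target_r2 < 1)
  if (is.null(drivers)) drivers <- generate_drivers(spec)
  ref <- drivers[[1]]
  d <- dim(ref$values)
  npix <- d[2] * d[3]
  X <- vapply(regression_drivers(),
              function(v) as.numeric(pixel_matrix(drivers[[v]])),
              numeric(d[1] * npix))
  smv <- as.numeric(pixel_matrix(drivers[["sm"]]))
  det <- matrix(wue_linear_predictor(X, spec, sm = smv), d[1], npix)
  var_signal <- mean(apply(det, 2L, stats::var))
  sqrt(var_signal * (1 - target_r2) / target_r2)
}

#' Ground-truth sidecar for a synthetic experiment
#'
#' Echoes the generating coefficients and breakpoints and records, for a
#' named period, the per-driver induced WUE change implied by the *realized*
#' driver trends: `beta_true_j x (OLS slope of the spatially averaged driver
#' series) x (n_years - 1)`. This is the reference the attribution stage's
#' closure is checked against.
#'
#' @param spec The [synthetic_spec()].
#' @param drivers The generated [driver_set()].
#' @param period Length-2 year range, e.g. `c(1983, 2014)`.
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(spec, drivers, period = c(1983, 2014)) {
  yrs <- drivers[[1]]$time
  sel <- yrs >= period[1] & yrs <= period[2]
  n <- sum(sel)
  changes <- vapply(regression_drivers(), function(v) {
    s <- spatial_mean(drivers[[v]])[sel]
    spec$true_beta[[v]] * ols_slope(s, yrs[sel]) * (n - 1)
  }, numeric(1))
  structure(
    list(beta_true = spec$true_beta,
         gamma_true = spec$interaction_gamma,
         breakpoints_true = spec$wind_breakpoints,
         per_driver_induced_change = changes,
         period = as.integer(period), n_years = n),
    class = "synthetic_truth"
  )
}

#' Generate a daily flux-site table
#'
#' Emulates a FLUXNET-style daily record for one grassland site: GPP, ET and
#' meteorology with a seasonal cycle, a controllable fraction of
#' negligible-water-flux days (ET below the screening threshold) and
#' injected high-WUE outliers above the site's 99th percentile — the
#' degenerate cases the two-step filter must catch.
#'
#' @param spec A [synthetic_spec()] (supplies meteorology levels and seed).
#' @param n_days Number of daily records (>= 1).
#' @param start_date First date (default start of the spec's year range).
#' @param negligible_frac Fraction of days forced to negligible ET.
#' @param negligible_et ET value (mm day-1) given to those days.
#' @param outlier_frac Fraction of days turned into high-WUE outliers.
#' @param site_id Site identifier string.
#' @return A `data.frame` with columns `site_id, date, gpp, et, wind, tair,
#'   pressure, precip, swrad, vpd, co2, qc_flag`; attribute `injected` lists
#'   the row indices of the constructed degenerate cases.
#' @export
generate_site_table <- function(spec, n_days,
                                start_date = as.Date(sprintf("%d-01-01",
                                                             min(spec$years))),
                                negligible_frac = 0,
                                negligible_et = 0.01,
                                outlier_frac = 0,
                                site_id = "SYN-001") {
  stopifnot(n_days >= 1)
  with_seed(derive_seed(spec$rng_seed, "site_table"), {
    dates <- seq(as.Date(start_date), by = "day", length.out = n_days)
    doy <- as.integer(format(dates, "%j"))
    season <- 0.5 - 0.5 * cos(2 * pi * (doy - 15) / 365.25)
    et <- pmax(0.3 + 3.2 * season + rnorm(n_days, 0, 0.4), 0.06)
    wue <- pmax(rnorm(n_days, 1.6, 0.35), 0.2)
    gpp <- et * wue
    m <- spec$driver_means
    s <- spec$driver_sds
    tab <- data.frame(
      site_id = site_id, date = dates, gpp = gpp, et = et,
      wind = pmax(rnorm(n_days, m[["wind"]], 3 * s[["wind"]]), 0.1),
      tair = m[["tair"]] + 8 * (season - 0.5) + rnorm(n_days, 0, 2),
      pressure = rnorm(n_days, m[["pressure"]], s[["pressure"]]),
      precip = round(pmax(rnorm(n_days, 1.2, 2), 0), 2),
      swrad = pmax(m[["swrad"]] * (0.4 + 1.2 * season) +
                     rnorm(n_days, 0, 15), 5),
      vpd = pmax(rnorm(n_days, m[["vpd"]], 3 * s[["vpd"]]), 0.01),
      co2 = rnorm(n_days, m[["co2"]], s[["co2"]]),
      qc_flag = 0L
    )
    n_negl <- round(negligible_frac * n_days)
    negl_idx <- if (n_negl > 0) sort(sample.int(n_days, n_negl)) else integer()
    tab$et[negl_idx] <- negligible_et
    n_out <- round(outlier_frac * n_days)
    pool <- setdiff(seq_len(n_days), negl_idx)
    out_idx <- if (n_out > 0) sort(sample(pool, n_out)) else integer()
    if (n_out > 0) {
      # push WUE far beyond the site's clean 99th percentile
      q99 <- stats::quantile(tab$gpp[pool] / tab$et[pool], 0.99, names = FALSE)
      tab$gpp[out_idx] <- tab$et[out_idx] * q99 * 3
    }
    attr(tab, "injected") <- list(negligible = negl_idx, outlier = out_idx)
    tab
  })
}

#' Generate static disturbance mask layers
#'
#' Human-footprint, burned-area and cultivated-fraction layers in which a
#' stated proportion of pixels exceeds the downstream exclusion thresholds
#' (50 / 30 / 30 on the percent scale); all remaining pixels sit safely
#' below them.
#'
#' @param grid_shape Integer `c(n_lat, n_lon)`.
#' @param fractions Named fractions in `[0, 1]` of pixels to push above each
#'   threshold: `human_footprint`, `burned_area`, `cultivated`.
#' @param rng_seed Integer seed.
#' @return An object of class `mask_layers`: three `n_lat x n_lon` matrices
#'   of fractions in `[0, 1]`, plus an `exceeds` list of logical matrices
#'   recording which pixels were constructed to exceed each threshold.
#' @export
generate_mask_layers <- function(grid_shape,
                                 fractions = c(human_footprint = 0,
                                               burned_area = 0,
                                               cultivated = 0),
                                 rng_seed = 1L) {
  fractions <- unlist(fractions)
  stopifnot(all(fractions >= 0), all(fractions <= 1))
  nlat <- grid_shape[1]; nlon <- grid_shape[2]
  npix <- nlat * nlon
  thresholds <- c(human_footprint = 0.50, burned_area = 0.30,
                  cultivated = 0.30)
  with_seed(rng_seed, {
    layers <- list()
    exceeds <- list()
    for (nm in names(thresholds)) {
      frac <- if (nm %in% names(fractions)) fractions[[nm]] else 0
      n_hi <- round(frac * npix)
      vals <- matrix(stats::runif(npix, 0, 0.8 * thresholds[[nm]]),
                     nlat, nlon)
      hi <- matrix(FALSE, nlat, nlon)
      if (n_hi > 0) {
        idx <- sample.int(npix, n_hi)
        vals[idx] <- stats::runif(n_hi, thresholds[[nm]] + 0.05,
                                  min(1, thresholds[[nm]] + 0.3))
        hi[idx] <- TRUE
      }
      layers[[nm]] <- vals
      exceeds[[nm]] <- hi
    }
    structure(c(layers, list(exceeds = exceeds)), class = "mask_layers")
  })
}
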
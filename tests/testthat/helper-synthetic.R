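# Shared fixtures, all built in code at test time.

# A small full-period world (fast to generate, big enough for summaries).
small_spec <- function(...) {
  synthetic_spec(grid_shape = c(4, 4), ...)
}

# A hand-built driver set on a single pixel: three years, simple values,
# used wherever arithmetic must be checkable by hand.
hand_drivers <- function() {
  yrs <- 2001:2003
  vals <- list(wind = c(3.0, 3.2, 2.9), tair = c(9, 10, 11),
               pressure = c(90, 90.5, 89.5), precip = c(400, 450, 500),
               swrad = c(175, 180, 185), vpd = c(0.8, 0.9, 0.7),
               co2 = c(370, 372, 374), sm = c(0.20, 0.18, 0.22))
  units <- c(wind = "m s-1", tair = "degC", pressure = "kPa",
             precip = "mm yr-1", swrad = "W m-2", vpd = "kPa",
             co2 = "ppm", sm = "m3 m-3")
  fields <- lapply(names(vals), function(v) {
    gridded_field(array(vals[[v]], c(3, 1, 1)), yrs, 45, 10, v, units[[v]])
  })
  names(fields) <- names(vals)
  driver_set(fields)
}

# Extract the time x 7 driver matrix of one pixel from a driver_set.
pixel_design <- function(drivers, px = 1L) {
  nt <- length(drivers[[1]]$time)
  X <- vapply(c("wind", "tair", "pressure", "precip", "swrad", "vpd", "co2"),
              function(v) matrix(drivers[[v]]$values, nt)[, px], numeric(nt))
  X
}

pixel_sm <- function(drivers, px = 1L) {
  nt <- length(drivers[[1]]$time)
  matrix(drivers[["sm"]]$values, nt)[, px]
}

pixel_wue <- function(wue, px = 1L) {
  nt <- length(wue$time)
  matrix(wue$values, nt)[, px]
}

# Deterministic triphasic series with optional iid noise.
triphasic_series <- function(noise_sd = 0, seed = 1,
                             spec = synthetic_spec(grid_shape = c(2, 2))) {
  mu <- wind_trajectory(spec)
  if (noise_sd > 0) {
    set.seed(seed)
    mu <- mu + rnorm(length(mu), 0, noise_sd)
  }
  list(values = mu, years = spec$years, breaks = spec$wind_breakpoints)
}
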
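# Contribution decomposition: driver-induced WUE changes (sensitivity x
# trend) and fractional contributions to the total WUE change.

#' Driver-induced WUE change over a period
#'
#' `change = beta * slope_per_year * (n_years - 1)`: the sensitivity times
#' the fitted-line endpoint difference of the driver over the period. A
#' negative sensitivity times a negative trend yields a positive induced
#' change (declining wind raising WUE).
#'
#' @param beta Sensitivity in g C kg-1 H2O per driver unit (vectorized).
#' @param slope_per_year Driver OLS trend, units per year.
#' @param n_years Number of years in the period.
#' @return Induced WUE change, g C kg-1 H2O.
#' @export
#' @examples
#' induced_change(-0.13, -0.0051, 17) # declining wind -> positive change
induced_change <- function(beta, slope_per_year, n_years) {
  beta * slope_per_year * (n_years - 1)
}

#' Per-driver fractional contributions
#'
#' Divides each driver's induced change by the total WUE change over the
#' same period, in percent. Drivers may contribute negatively (as VPD does
#' when it rises while its sensitivity is negative). The unexplained
#' residual share is reported explicitly. When the total change is below
#' `floor` in magnitude the fractions are undefined (`NA`) rather than
#' exploding.
#'
#' @param per_driver_change Named vector of induced changes, g C kg-1 H2O.
#' @param total_change Total WUE change over the period (fitted-line
#'   endpoint difference, for consistency with the driver side).
#' @param floor Degenerate-total magnitude floor (default 1e-6).
#' @return List: `fraction` (named percents), `residual` (g C kg-1 H2O),
#'   `residual_fraction` (percent).
#' @export
fractional_contribution <- function(per_driver_change, total_change,
                                    floor = 1e-6) {
  residual <- total_change - sum(per_driver_change, na.rm = TRUE)
  if (!is.finite(total_change) || abs(total_change) < floor) {
    frac <- per_driver_change * NA_real_
    rf <- NA_real_
  } else {
    frac <- 100 * per_driver_change / total_change
    rf <- 100 * residual / total_change
  }
  list(fraction = frac, residual = residual, residual_fraction = rf)
}

#' Attribute a WUE change to its climatic drivers
#'
#' Combines per-driver sensitivities with per-driver trends into induced
#' changes and fractional contributions over one period, for one dataset or
#' scenario.
#'
#' @param beta Named sensitivities (one per driver), original units.
#' @param driver_slopes Named driver trends, units per year, same names.
#' @param wue_slope WUE trend over the same period, g C kg-1 H2O per year.
#' @param n_years Years in the period.
#' @param scenario_label Optional label carried into tables.
#' @param floor Degenerate-total floor, see [fractional_contribution()].
#' @return Object of class `wue_attribution`: `per_driver_change`,
#'   `total_change`, `per_driver_fraction`, `residual`,
#'   `residual_fraction`, `n_years`, `scenario_label`.
#' @export
attribute_drivers <- function(beta, driver_slopes, wue_slope, n_years,
                              scenario_label = "default", floor = 1e-6) {
  drivers <- names(beta)
  stopifnot(!is.null(drivers), all(drivers %in% names(driver_slopes)))
  changes <- induced_change(beta, driver_slopes[drivers], n_years)
  total <- wue_slope * (n_years - 1)
  fc <- fractional_contribution(changes, total, floor = floor)
  structure(
    list(per_driver_change = changes, total_change = total,
         per_driver_fraction = fc$fraction, residual = fc$residual,
         residual_fraction = fc$residual_fraction,
         n_years = n_years, scenario_label = scenario_label),
    class = "wue_attribution"
  )
}

#' @export
print.wue_attribution <- function(x, ...) {
  cat(sprintf("<wue_attribution> %s: total %.4g g C kg-1 H2O over %d years\n",
              x$scenario_label, x$total_change, x$n_years))
  tab <- data.frame(change = round(x$per_driver_change, 5),
                    percent = round(x$per_driver_fraction, 2))
  print(tab)
  cat(sprintf("  residual: %.4g (%.2f%%)\n", x$residual,
              x$residual_fraction))
  invisible(x)
}

#' Drivers-by-scenarios contribution table
#'
#' Assembles several [attribute_drivers()] results into matrices of
#' fractional contributions (percent) and induced changes, one column per
#' scenario. Missing scenarios are allowed (columns of `NA`).
#'
#' @param attributions Named list of `wue_attribution` objects (names are
#'   scenario labels; unnamed entries use their `scenario_label`).
#' @return List with matrices `fraction` and `change`
#'   (drivers + `residual` rows x scenarios).
#' @export
scenario_table <- function(attributions) {
  stopifnot(length(attributions) >= 1L)
  labs <- names(attributions)
  if (is.null(labs) || any(!nzchar(labs))) {
    labs <- vapply(attributions, function(a) a$scenario_label, character(1))
  }
  drivers <- names(attributions[[1]]$per_driver_change)
  frac <- matrix(NA_real_, length(drivers) + 1L, length(attributions),
                 dimnames = list(c(drivers, "residual"), labs))
  chg <- frac
  for (i in seq_along(attributions)) {
    a <- attributions[[i]]
    if (is.null(a)) next
    stopifnot(identical(names(a$per_driver_change), drivers))
    frac[drivers, i] <- a$per_driver_fraction
    frac["residual", i] <- a$residual_fraction
    chg[drivers, i] <- a$per_driver_change
    chg["residual", i] <- a$residual
  }
  list(fraction = frac, change = chg)
}

#' Per-pixel induced-change map
#'
#' Elementwise `beta * slope * (n_years - 1)` over coefficient and trend
#' maps, for mapping where a driver raised or lowered WUE.
#'
#' @param beta_map Matrix of per-pixel sensitivities.
#' @param slope_map Matrix of per-pixel driver slopes (per year).
#' @param n_years Years in the period.
#' @return Matrix of induced changes (`NA` where either input is missing).
#' @export
induced_change_map <- function(beta_map, slope_map, n_years) {
  stopifnot(identical(dim(beta_map), dim(slope_map)))
  induced_change(beta_map, slope_map, n_years)
}
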
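#' Gridded field container
#'
#' A single variable on a regular (time, lat, lon) grid with units and an
#' implicit missing-value mask (`NA`). This is the basic carrier for the
#' response (WUE) and each climatic driver.
#'
#' @param values Numeric array with dimensions `(time, lat, lon)`.
#' @param time Numeric time axis (calendar years, or fractional years for
#'   monthly data), strictly increasing, one entry per time slice.
#' @param lat,lon Numeric cell-centre coordinates (degrees).
#' @param name Variable identifier.
#' @param units Physical unit string (required; unknown-unit fields are
#'   rejected by I/O and ratio operations rather than guessed).
#' @return An object of class `gridded_field`.
#' @export
#' @examples
#' gf <- gridded_field(array(1, c(3, 2, 2)), time = 2001:2003,
#'                     lat = c(40, 41), lon = c(10, 11),
#'                     name = "wind", units = "m s-1")
#' dim(gf$values)
gridded_field <- function(values, time, lat, lon, name, units) {
  values <- as.array(values)
  if (length(dim(values)) != 3L) {
    stop("`values` must be a (time, lat, lon) array", call. = FALSE)
  }
  if (dim(values)[1] != length(time) || dim(values)[2] != length(lat) ||
      dim(values)[3] != length(lon)) {
    stop("array dimensions do not match time/lat/lon axes", call. = FALSE)
  }
  if (anyNA(time) || is.unsorted(time, strictly = TRUE)) {
    stop("`time` must be strictly increasing with no duplicates", call. = FALSE)
  }
  if (missing(units) || is.null(units) || !nzchar(units)) {
    stop("`units` is required for a gridded field", call. = FALSE)
  }
  structure(
    list(name = name, values = values, units = units,
         time = as.numeric(time), lat = as.numeric(lat),
         lon = as.numeric(lon)),
    class = "gridded_field"
  )
}

#' @export
print.gridded_field <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<gridded_field> %s [%s]  %d time x %d lat x %d lon  (%.4g..%.4g)\n",
              x$name, x$units, d[1], d[2], d[3],
              suppressWarnings(min(x$values, na.rm = TRUE)),
              suppressWarnings(max(x$values, na.rm = TRUE))))
  invisible(x)
}

# time x pixel matrix view (pixels in column-major (lat, lon) order)
pixel_matrix <- function(field) {
  d <- dim(field$values)
  matrix(field$values, nrow = d[1], ncol = d[2] * d[3])
}

#' Area weights for a latitude axis
#'
#' Cosine-of-latitude weights used for spatial averaging on a regular
#' lon-lat grid, expanded to one weight per pixel.
#'
#' @param lat,lon Cell-centre coordinates (degrees).
#' @return Numeric vector of length `length(lat) * length(lon)` summing to 1.
#' @export
cosine_weights <- function(lat, lon) {
  w <- rep(cos(lat * pi / 180), times = length(lon))
  w / sum(w)
}

#' Spatially averaged series of a gridded field
#'
#' Cosine-latitude-weighted mean over all non-missing pixels for each time
#' step (the "thick line" summary of a field's anomaly trajectory).
#'
#' @param field A [gridded_field()].
#' @param weights Optional pixel weights; defaults to cosine-latitude.
#' @return Numeric vector along `field$time`.
#' @export
spatial_mean <- function(field, weights = NULL) {
  m <- pixel_matrix(field)
  w <- weights %||% cosine_weights(field$lat, field$lon)
  apply(m, 1L, function(row) {
    ok <- is.finite(row)
    if (!any(ok)) return(NA_real_)
    sum(row[ok] * w[ok]) / sum(w[ok])
  })
}

#' Anomalies of a gridded field relative to a baseline period
#'
#' Subtracts, per pixel, the mean over the baseline years. Anomaly is linear
#' and removes any constant offset; with the full period as baseline each
#' pixel's anomaly series sums to zero.
#'
#' @param field A [gridded_field()].
#' @param baseline Length-2 numeric `c(first, last)` year of the baseline,
#'   inclusive. Default: the field's full span.
#' @return A `gridded_field` of anomalies (same units), with an extra
#'   attribute `baseline_mean` holding the per-pixel baseline-mean matrix.
#' @export
anomaly <- function(field, baseline = range(field$time)) {
  sel <- field$time >= baseline[1] & field$time <= baseline[2]
  if (!any(sel)) stop("baseline period contains no time steps", call. = FALSE)
  m <- pixel_matrix(field)
  base <- colMeans(m[sel, , drop = FALSE], na.rm = TRUE)
  out <- sweep(m, 2L, base, "-")
  d <- dim(field$values)
  res <- gridded_field(array(out, d), field$time, field$lat, field$lon,
                       paste0(field$name, "_anom"), field$units)
  attr(res, "baseline_mean") <- matrix(base, d[2], d[3])
  res
}

#' Aligned set of climatic driver fields
#'
#' Bundles several [gridded_field()]s on one common grid and time axis. The
#' canonical driver set holds the seven regression drivers
#' (`wind, tair, pressure, precip, swrad, vpd, co2`) plus soil moisture
#' (`sm`).
#'
#' @param ... Named `gridded_field` objects (or a single named list).
#' @return An object of class `driver_set` (named list of fields).
#' @export
driver_set <- function(...) {
  fields <- list(...)
  if (length(fields) == 1L && !inherits(fields[[1]], "gridded_field")) {
    fields <- fields[[1]]
  }
  if (is.null(names(fields)) || any(!nzchar(names(fields)))) {
    stop("all driver fields must be named", call. = FALSE)
  }
  ref <- fields[[1]]
  for (f in fields) {
    if (!inherits(f, "gridded_field")) {
      stop("driver_set components must be gridded_field objects", call. = FALSE)
    }
    if (!identical(f$time, ref$time) || !identical(f$lat, ref$lat) ||
        !identical(f$lon, ref$lon)) {
      stop("all fields in a driver_set must share one grid and time axis",
           call. = FALSE)
    }
  }
  structure(fields, class = "driver_set")
}

#' @export
print.driver_set <- function(x, ...) {
  d <- dim(x[[1]]$values)
  cat(sprintf("<driver_set> %d fields (%s) on %d x %d x %d\n",
              length(x), paste(names(x), collapse = ", "), d[1], d[2], d[3]))
  invisible(x)
}

#' Restrict a field or driver set to a year range
#'
#' @param x A [gridded_field()] or [driver_set()].
#' @param period Length-2 inclusive `c(first, last)` along the time axis.
#' @return The input restricted to time steps inside `period`.
#' @export
subset_years <- function(x, period) {
  if (inherits(x, "driver_set")) {
    return(driver_set(lapply(x, subset_years, period = period)))
  }
  stopifnot(inherits(x, "gridded_field"))
  sel <- x$time >= period[1] & x$time <= period[2]
  if (!any(sel)) stop("no time steps inside the period", call. = FALSE)
  gridded_field(x$values[sel, , , drop = FALSE], x$time[sel], x$lat, x$lon,
                x$name, x$units)
}

# The seven regression drivers, in canonical order.
regression_drivers <- function() {
  c("wind", "tair", "pressure", "precip", "swrad", "vpd", "co2")
}
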
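# Preprocessing: the WUE ratio, the two-step site filter, station coverage
# screening, Buck-equation VPD, soil-layer averaging, the grassland
# disturbance mask, and anomaly/trend plumbing.

wue_unit_ok <- function(units) {
  # 1 mm of water over 1 m^2 is 1 kg, so GPP [g C m-2] / ET [mm] is
  # directly g C per kg H2O.
  gsub("\\s+", " ", tolower(units))
}

#' Compute ecosystem water-use efficiency
#'
#' WUE = GPP / ET in g C kg-1 H2O (1 mm ET is 1 kg H2O m-2). Works on two
#' aligned [gridded_field()]s or on plain numeric vectors. Cells with
#' missing or non-positive ET become missing — never infinite. Monthly or
#' annual inputs are treated identically; no VPD correction is applied at
#' these time scales (that adjustment belongs to subdaily estimators).
#'
#' @param gpp GPP, g C m-2 per time step ([gridded_field()] or numeric).
#' @param et ET, mm per time step (same shape as `gpp`).
#' @return WUE with the same shape, units g C kg-1 H2O.
#' @export
#' @examples
#' compute_wue(120, 60) # 2 g C per kg water
compute_wue <- function(gpp, et) {
  if (inherits(gpp, "gridded_field") && inherits(et, "gridded_field")) {
    if (!identical(gpp$time, et$time) || !identical(gpp$lat, et$lat) ||
        !identical(gpp$lon, et$lon)) {
      stop("GPP and ET fields are not aligned", call. = FALSE)
    }
    gu <- wue_unit_ok(gpp$units)
    eu <- wue_unit_ok(et$units)
    if (!grepl("^g c m-2", gu)) {
      stop(sprintf("GPP units must be g C m-2 per time step, got '%s'",
                   gpp$units), call. = FALSE)
    }
    if (!grepl("^(mm|kg h2o m-2|kg m-2)", eu)) {
      stop(sprintf("ET units must be mm (kg H2O m-2) per time step, got '%s'",
                   et$units), call. = FALSE)
    }
    vals <- gpp$values / et$values
    vals[!is.finite(vals) | et$values <= 0] <- NA_real_
    return(gridded_field(vals, gpp$time, gpp$lat, gpp$lon, "wue",
                         "g C kg-1 H2O"))
  }
  out <- as.numeric(gpp) / as.numeric(et)
  out[!is.finite(out) | as.numeric(et) <= 0] <- NA_real_
  out
}

#' Aggregate monthly fluxes to annual WUE
#'
#' Annual WUE is the flux-weighted ratio of annual totals,
#' `sum(GPP) / sum(ET)` — not the mean of monthly ratios, which overweights
#' low-flux months. The two differ whenever WUE covaries with ET.
#'
#' @param gpp,et Monthly values (numeric).
#' @param year Integer year label per monthly value.
#' @return Data frame with columns `year`, `wue`.
#' @export
annual_wue <- function(gpp, et, year) {
  stopifnot(length(gpp) == length(et), length(gpp) == length(year))
  g <- tapply(gpp, year, sum, na.rm = TRUE)
  e <- tapply(et, year, sum, na.rm = TRUE)
  data.frame(year = as.integer(names(g)),
             wue = compute_wue(as.numeric(g), as.numeric(e)),
             row.names = NULL)
}

#' Two-step screening of daily flux records
#'
#' Step 1 removes days with negligible water flux (ET below `et_min`), where
#' the GPP/ET ratio is a mathematical artifact. Step 2 removes days whose
#' WUE strictly exceeds the per-site 99th percentile, computed on the
#' records that *survive* step 1 — the order matters and is part of the
#' procedure's definition.
#'
#' @param table Site table (as from [generate_site_table()]) with columns
#'   `gpp`, `et` and optionally `site_id` (the percentile is per site).
#' @param et_min Negligible-flux threshold, mm day-1 (default 0.05).
#' @param wue_quantile Outlier percentile (default 0.99).
#' @param quantile_type Sample-quantile convention passed to
#'   [stats::quantile()] (default 7, the linear-interpolation estimator).
#' @return List with `table` (filtered, with a `wue` column) and `report`
#'   (`n_input`, `n_removed_et`, `n_removed_wue`, `n_kept`, thresholds
#'   used).
#' @export
filter_site_records <- function(table, et_min = 0.05, wue_quantile = 0.99,
                                quantile_type = 7) {
  n_input <- nrow(table)
  if (n_input == 0L) {
    return(list(table = table,
                report = list(n_input = 0L, n_removed_et = 0L,
                              n_removed_wue = 0L, n_kept = 0L,
                              et_min = et_min, wue_quantile = wue_quantile)))
  }
  keep_et <- !is.na(table$et) & table$et >= et_min
  step1 <- table[keep_et, , drop = FALSE]
  step1$wue <- compute_wue(step1$gpp, step1$et)
  site <- if ("site_id" %in% names(step1)) step1$site_id else rep("site", nrow(step1))
  drop_wue <- logical(nrow(step1))
  for (s in unique(site)) {
    i <- which(site == s & !is.na(step1$wue))
    if (length(i) == 0L) next
    q99 <- stats::quantile(step1$wue[i], wue_quantile, names = FALSE,
                           type = quantile_type)
    drop_wue[i[step1$wue[i] > q99]] <- TRUE
  }
  out <- step1[!drop_wue, , drop = FALSE]
  list(table = out,
       report = list(n_input = n_input,
                     n_removed_et = n_input - nrow(step1),
                     n_removed_wue = sum(drop_wue),
                     n_kept = nrow(out),
                     et_min = et_min, wue_quantile = wue_quantile))
}

#' Station coverage screening
#'
#' A station is kept only if its record spans the whole target period with
#' complete records for all 12 calendar months of every year and at least
#' `min_valid_days` valid observation days in every month. Any shortfall in
#' any month is fatal for the station (the strict reading of continuous
#' coverage).
#'
#' @param dates `Date` vector of daily observations.
#' @param valid Logical validity flag per day (default all valid).
#' @param period Integer `c(first, last)` year, default `c(1983, 2023)`.
#' @param min_valid_days Minimum valid days per calendar month (default 15).
#' @return List with `keep` (logical) and `reason` (string, `""` if kept).
#' @export
screen_station <- function(dates, valid = rep(TRUE, length(dates)),
                           period = c(1983, 2023), min_valid_days = 15L) {
  years <- as.integer(format(dates, "%Y"))
  months <- as.integer(format(dates, "%m"))
  want_years <- seq(period[1], period[2])
  in_period <- years %in% want_years
  for (yr in want_years) {
    present <- sort(unique(months[in_period & years == yr]))
    if (length(present) < 12L) {
      return(list(keep = FALSE,
                  reason = sprintf("year %d missing calendar month(s) %s", yr,
                                   paste(setdiff(1:12, present),
                                         collapse = ","))))
    }
    for (mo in 1:12) {
      nv <- sum(valid[in_period & years == yr & months == mo])
      if (nv < min_valid_days) {
        return(list(keep = FALSE,
                    reason = sprintf("month below minimum valid days (%d-%02d: %d < %d)",
                                     yr, mo, nv, min_valid_days)))
      }
    }
  }
  list(keep = TRUE, reason = "")
}

#' Buck-equation constants (over water)
#'
#' The 1981 Buck fit for saturation vapour pressure over liquid water
#' (`e_w1`: a exp(b T / (T + c)), a in kPa) and its pressure enhancement
#' factor `f_w = A + B P` with P in kPa. Isolated here so the variant in use
#' is auditable in one place.
#' @return Named list of constants.
#' @export
buck_constants <- function() {
  list(a = 0.61121,   # kPa
       b = 17.502,
       c = 240.97,    # degC
       f_A = 1.0007,
       f_B = 3.46e-5) # per kPa of air pressure
}

#' Vapour pressure deficit from the Buck equation
#'
#' `VPD = f_w(P) * e_s(T) * (1 - RH/100)` with the over-water Buck
#' saturation formula and its pressure enhancement factor. Exactly zero at
#' saturation and monotonically increasing in temperature below saturation.
#'
#' @param tair Air temperature, degC.
#' @param pressure Air pressure, kPa.
#' @param rh Relative humidity, percent in `[0, 100]`.
#' @return VPD in kPa (>= 0).
#' @export
#' @examples
#' buck_vpd(20, 101.325, 50)
buck_vpd <- function(tair, pressure, rh) {
  if (any(rh < 0 | rh > 100, na.rm = TRUE)) {
    stop("relative humidity must be in [0, 100] percent", call. = FALSE)
  }
  k <- buck_constants()
  es <- (k$f_A + k$f_B * pressure) * k$a * exp(k$b * tair / (tair + k$c))
  pmax(es * (1 - rh / 100), 0)
}

#' Thickness-weighted soil-moisture mean over a target depth range
#'
#' Averages per-layer soil moisture weighted by each layer's thickness of
#' overlap with the target interval (default 0-28 cm); layers that only
#' partly overlap are clipped to their overlapping thickness.
#'
#' @param layer_values Numeric soil moisture per layer.
#' @param layer_bounds Two-column matrix (or list of length-2 vectors) of
#'   layer depth intervals (top, bottom), ordered and non-overlapping, same
#'   length units as `target`.
#' @param target Length-2 target depth interval, default `c(0, 28)` cm.
#' @return Weighted mean, or `NA` if no layer overlaps the target range.
#' @export
#' @examples
#' sm_weighted_mean(c(0.30, 0.20), rbind(c(0, 10), c(10, 28)))
sm_weighted_mean <- function(layer_values, layer_bounds, target = c(0, 28)) {
  if (is.list(layer_bounds)) layer_bounds <- do.call(rbind, layer_bounds)
  stopifnot(ncol(layer_bounds) == 2L,
            nrow(layer_bounds) == length(layer_values))
  if (any(layer_bounds[, 2] <= layer_bounds[, 1])) {
    stop("layer bounds must have top < bottom", call. = FALSE)
  }
  if (is.unsorted(layer_bounds[, 1]) ||
      any(layer_bounds[-1, 1] < layer_bounds[-nrow(layer_bounds), 2] - 1e-9)) {
    stop("layers must be ordered by depth and non-overlapping", call. = FALSE)
  }
  w <- pmax(pmin(layer_bounds[, 2], target[2]) -
              pmax(layer_bounds[, 1], target[1]), 0)
  if (sum(w) <= 0) return(NA_real_)
  sum(w * layer_values) / sum(w)
}

#' Pixel retention mask from disturbance layers
#'
#' A pixel is excluded when ANY of the three disturbance criteria holds, on
#' the percent scale with strict inequalities: human footprint > 50,
#' burned area > 30, or cultivated/managed cover > 30. Values exactly at a
#' threshold are retained.
#'
#' @param mask A [generate_mask_layers()] object (fractions in `[0, 1]`).
#' @param thresholds Named percent thresholds.
#' @return Logical matrix, `TRUE` where the pixel is kept.
#' @export
grassland_keep_mask <- function(mask,
                                thresholds = c(human_footprint = 50,
                                               burned_area = 30,
                                               cultivated = 30)) {
  drop <- (mask$human_footprint * 100 > thresholds[["human_footprint"]]) |
    (mask$burned_area * 100 > thresholds[["burned_area"]]) |
    (mask$cultivated * 100 > thresholds[["cultivated"]])
  !drop
}

#' Apply the grassland disturbance mask to fields
#'
#' Sets every time step of excluded pixels to missing. Masking is
#' idempotent.
#'
#' @param fields A [driver_set()] or single [gridded_field()].
#' @param mask A [generate_mask_layers()] object.
#' @param thresholds Percent thresholds, see [grassland_keep_mask()].
#' @return The input with excluded pixels set `NA` throughout.
#' @export
apply_grassland_mask <- function(fields, mask,
                                 thresholds = c(human_footprint = 50,
                                                burned_area = 30,
                                                cultivated = 30)) {
  keep <- grassland_keep_mask(mask, thresholds)
  mask_one <- function(f) {
    stopifnot(identical(dim(f$values)[2:3], dim(keep)))
    v <- f$values
    for (t in seq_len(dim(v)[1])) {
      slice <- v[t, , ]
      slice[!keep] <- NA_real_
      v[t, , ] <- slice
    }
    gridded_field(v, f$time, f$lat, f$lon, f$name, f$units)
  }
  if (inherits(fields, "gridded_field")) return(mask_one(fields))
  driver_set(lapply(fields, mask_one))
}
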
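# Per-pixel application of the PCR estimator over a grid, plus the
# multi-dataset ensemble average.

#' Per-pixel PCR sensitivity maps
#'
#' Runs [estimate_sensitivity()] independently at every pixel of the grid,
#' optionally with the Wind/SM interaction term, and returns one coefficient
#' layer per driver plus diagnostic layers. Pixels with fewer complete
#' years than `min_years` are missing in every layer.
#'
#' @param wue WUE response [gridded_field()].
#' @param drivers A [driver_set()] containing the seven regression drivers
#'   (and `sm` when `interaction = TRUE`).
#' @param var_threshold,min_years See [estimate_sensitivity()].
#' @param interaction Add the Wind/SM ratio as an eighth predictor?
#' @param mc_reps If > 0, also run [monte_carlo_uncertainty()] per pixel
#'   with this many replicates.
#' @param seed Seed for the Monte Carlo stage (per-pixel child seeds are
#'   derived from it).
#' @return Object of class `sensitivity_map`: list with `beta` (named list
#'   of lat x lon matrices, one per driver), `interaction_beta`, `r_squared`,
#'   `p_retained`, `n_years`, and when requested `mc_relative_uncertainty`
#'   and `mc_mean_r2`; plus `lat`, `lon`.
#' @export
sensitivity_grid <- function(wue, drivers, var_threshold = 0.85,
                             min_years = 10L, interaction = FALSE,
                             mc_reps = 0L, seed = 1L) {
  stopifnot(inherits(wue, "gridded_field"), inherits(drivers, "driver_set"))
  d <- dim(wue$values)
  npix <- d[2] * d[3]
  Y <- pixel_matrix(wue)
  Xs <- lapply(regression_drivers(), function(v) pixel_matrix(drivers[[v]]))
  names(Xs) <- regression_drivers()
  SM <- if (interaction) pixel_matrix(drivers[["sm"]]) else NULL

  layer <- function() matrix(NA_real_, d[2], d[3])
  beta_maps <- stats::setNames(replicate(7, layer(), simplify = FALSE),
                               regression_drivers())
  inter_map <- layer(); r2_map <- layer(); p_map <- layer(); n_map <- layer()
  mc_unc <- layer(); mc_r2 <- layer()

  for (px in seq_len(npix)) {
    y <- Y[, px]
    X <- vapply(Xs, function(m) m[, px], numeric(d[1]))
    sm <- if (interaction) SM[, px] else NULL
    fit <- suppressWarnings(
      tryCatch(estimate_sensitivity(y, X, var_threshold, min_years, sm = sm),
               error = function(e) NULL))
    if (is.null(fit)) next
    for (v in regression_drivers()) beta_maps[[v]][px] <- fit$beta[[v]]
    inter_map[px] <- fit$interaction_beta
    r2_map[px] <- fit$r_squared
    p_map[px] <- fit$p_retained
    n_map[px] <- fit$n_years
    if (mc_reps > 0L) {
      mc <- tryCatch(
        suppressWarnings(
          monte_carlo_uncertainty(y, X, n_rep = mc_reps,
                                  seed = derive_seed(seed,
                                                     paste0("mc_px", px)),
                                  var_threshold = var_threshold,
                                  min_years = min_years, sm = sm)),
        error = function(e) NULL)
      if (!is.null(mc)) {
        mc_unc[px] <- mc$relative_uncertainty
        mc_r2[px] <- mc$mean_r2
      }
    }
  }
  out <- list(beta = beta_maps, interaction_beta = inter_map,
              r_squared = r2_map, p_retained = p_map, n_years = n_map,
              lat = wue$lat, lon = wue$lon,
              var_threshold = var_threshold, min_years = min_years)
  if (mc_reps > 0L) {
    out$mc_relative_uncertainty <- mc_unc
    out$mc_mean_r2 <- mc_r2
  }
  structure(out, class = "sensitivity_map")
}

#' @export
print.sensitivity_map <- function(x, ...) {
  cat(sprintf("<sensitivity_map> %d x %d pixels, %d estimated; median dWUE/dWind = %.4f\n",
              nrow(x$r_squared), ncol(x$r_squared),
              sum(is.finite(x$r_squared)),
              stats::median(x$beta$wind, na.rm = TRUE)))
  invisible(x)
}

#' Fraction of pixels with a negative value
#'
#' Percent of non-missing pixels (optionally cosine-latitude weighted) whose
#' value is negative; used for summaries such as the share of pixels with
#' negative wind sensitivity or negative trends.
#'
#' @param values Matrix of per-pixel values (lat x lon).
#' @param p_values Optional matrix of p-values; with `significant_only`
#'   restricts the count to `p < alpha`.
#' @param significant_only Count only statistically significant pixels?
#' @param alpha Significance level (default 0.05).
#' @param lat,lon Optional axes for cosine-latitude weighting (unweighted
#'   when omitted).
#' @return Percent in `[0, 100]` (`NA` when nothing is countable).
#' @export
negative_fraction <- function(values, p_values = NULL,
                              significant_only = FALSE, alpha = 0.05,
                              lat = NULL, lon = NULL) {
  v <- as.numeric(values)
  ok <- is.finite(v)
  if (significant_only) {
    stopifnot(!is.null(p_values))
    ok <- ok & is.finite(as.numeric(p_values)) & as.numeric(p_values) < alpha
  }
  if (!any(ok)) return(NA_real_)
  w <- if (is.null(lat)) rep(1, length(v)) else cosine_weights(lat, lon)
  100 * sum(w[ok & v < 0]) / sum(w[ok])
}

#' Missing-aware ensemble average of sensitivity layers
#'
#' Per-pixel unweighted mean over datasets or models: at each pixel the mean
#' of the layers that are non-missing there (e.g. the three reanalysis wind
#' products, or the CMIP6 models).
#'
#' @param layers List of congruent matrices (or numeric vectors).
#' @return Matrix (or vector) of per-pixel means; `NA` only where every
#'   layer is missing.
#' @export
#' @examples
#' ensemble_average(list(matrix(-0.13), matrix(-0.14), matrix(-0.10)))
ensemble_average <- function(layers) {
  stopifnot(length(layers) >= 1L)
  ref <- layers[[1]]
  for (l in layers) stopifnot(identical(dim(l), dim(ref)))
  acc <- array(0, dim = dim(ref) %||% length(ref))
  cnt <- array(0L, dim = dim(ref) %||% length(ref))
  for (l in layers) {
    ok <- is.finite(l)
    acc[ok] <- acc[ok] + l[ok]
    cnt[ok] <- cnt[ok] + 1L
  }
  out <- acc / cnt
  out[cnt == 0L] <- NA_real_
  if (is.null(dim(ref))) out <- as.numeric(out)
  out
}
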
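# Principal-components regression sensitivity estimation: z-score
# standardization, PCA on the standardized drivers, OLS in component space,
# and the back-transformation to original-unit coefficients, plus bootstrap
# (Monte Carlo) uncertainty and the Wind/SM interaction extension.

#' Standardize a regression design
#'
#' Z-score normalization of the response and each driver column, storing the
#' means and SDs for exact inversion. Zero-variance columns (for example CO2
#' over a short window) are recorded as dropped, never silently zero-filled.
#'
#' @param y Numeric response series (no missing values; callers remove
#'   incomplete years first).
#' @param X Numeric matrix of drivers, one column per driver, named.
#' @return List of class `pcr_design`: `y_star`, `x_star` (kept columns),
#'   `kept`, `dropped`, `ym`, `ys`, `xm`, `xs`.
#' @export
zscore_design <- function(y, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (anyNA(y) || anyNA(X)) {
    stop("zscore_design requires complete cases; drop missing years first",
         call. = FALSE)
  }
  if (length(y) != nrow(X)) stop("y and X differ in length", call. = FALSE)
  ym <- mean(y)
  ys <- stats::sd(y)
  if (!is.finite(ys) || ys <= 0) {
    stop("response has zero variance; sensitivity undefined", call. = FALSE)
  }
  xm <- colMeans(X)
  xs <- apply(X, 2L, stats::sd)
  tol <- 1e-12
  dropped <- colnames(X)[!is.finite(xs) | xs <= tol]
  if (length(dropped)) {
    warning(sprintf("zero-variance driver column(s) dropped: %s",
                    paste(dropped, collapse = ", ")), call. = FALSE)
  }
  kept <- setdiff(colnames(X), dropped)
  x_star <- sweep(sweep(X[, kept, drop = FALSE], 2L, xm[kept], "-"),
                  2L, xs[kept], "/")
  structure(list(y_star = (y - ym) / ys, x_star = x_star,
                 kept = kept, dropped = dropped,
                 ym = ym, ys = ys, xm = xm, xs = xs),
            class = "pcr_design")
}

#' Principal components of a standardized design
#'
#' PCA on the correlation structure of the standardized driver matrix
#' (equivalently, the covariance of the z-scores). Components are ranked by
#' explained variance and the smallest count whose cumulative fraction
#' strictly exceeds `threshold` is retained; if the first component alone
#' exceeds it, one is kept; the count never exceeds the design's rank. The
#' sign of each loading column is fixed by making its largest-magnitude
#' element positive (the back-transformation is invariant to this choice).
#'
#' @param design A [zscore_design()].
#' @param threshold Cumulative explained-variance retention threshold
#'   (default 0.85, strict inequality).
#' @return List of class `pcr_basis`: `loadings` (columns orthonormal),
#'   `explained_variance` (all components), `p` (retained count).
#' @export
fit_components <- function(design, threshold = 0.85) {
  stopifnot(inherits(design, "pcr_design"))
  x <- design$x_star
  if (nrow(x) < 2L) stop("need at least 2 observations for PCA", call. = FALSE)
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  rank <- sum(pc$sdev > max(pc$sdev) * 1e-9)
  p <- which(cumsum(ev) > threshold)[1]
  if (is.na(p)) p <- rank
  p <- min(max(p, 1L), rank)
  L <- pc$rotation
  for (k in seq_len(ncol(L))) {
    j <- which.max(abs(L[, k]))
    if (L[j, k] < 0) L[, k] <- -L[, k]
  }
  structure(list(loadings = L, explained_variance = ev, p = p, rank = rank),
            class = "pcr_basis")
}

#' Component-space regression
#'
#' Ordinary least squares of the standardized response on the `p` retained
#' component scores. With centred inputs the intercept is numerically zero.
#'
#' @param design A [zscore_design()].
#' @param basis A [fit_components()] basis from the same design.
#' @return List: `beta0_star`, `beta_star` (length `p`), `fitted`,
#'   `r_squared`.
#' @export
pcr_regress <- function(design, basis) {
  stopifnot(inherits(design, "pcr_design"), inherits(basis, "pcr_basis"))
  Z <- design$x_star %*% basis$loadings[, seq_len(basis$p), drop = FALSE]
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, Z), design$y_star)
  coefs <- fit$coefficients
  coefs[is.na(coefs)] <- 0
  fitted <- drop(cbind(1, Z) %*% coefs)
  tss <- sum((design$y_star - mean(design$y_star))^2)
  rss <- sum((design$y_star - fitted)^2)
  list(beta0_star = coefs[1], beta_star = coefs[-1], fitted = fitted,
       r_squared = if (tss > 0) max(0, min(1, 1 - rss / tss)) else NA_real_)
}

#' Back-transform component coefficients to original units
#'
#' Reverses the PCA and the z-score normalization:
#' `beta_j = (ys / xs_j) * sum_k loadings[j, k] * beta_star_k` and
#' `beta0 = ym - sum_j beta_j * xm_j`. Columns dropped for zero variance
#' receive `NA` (undefined), not zero. With all components retained this
#' reproduces direct least squares exactly.
#'
#' @param beta_star Component-space coefficients (length `basis$p`).
#' @param basis The [fit_components()] basis.
#' @param design The [zscore_design()].
#' @return List: `beta0`, `beta` (named over all original columns, `NA`
#'   where undefined).
#' @export
backtransform <- function(beta_star, basis, design) {
  L <- basis$loadings[, seq_len(basis$p), drop = FALSE]
  b_std <- drop(L %*% beta_star) # coefficients on the z-scored drivers
  all_cols <- names(design$xm)
  beta <- stats::setNames(rep(NA_real_, length(all_cols)), all_cols)
  beta[design$kept] <- design$ys * b_std / design$xs[design$kept]
  beta0 <- design$ym - sum(beta[design$kept] * design$xm[design$kept])
  list(beta0 = beta0, beta = beta)
}

#' Estimate WUE sensitivities for one pixel or site
#'
#' Full PCR pipeline: drop incomplete years, standardize, decompose, regress
#' in component space, back-transform. The entry for wind is the sensitivity
#' of WUE to wind speed in g C kg-1 H2O per m s-1. With `sm` supplied, the
#' ratio Wind/SM enters as an eighth predictor and its coefficient is
#' returned as `interaction_beta`; pixel-years with non-positive soil
#' moisture are dropped before regression (the ratio is undefined there).
#'
#' @param y WUE series (annual values).
#' @param X Driver matrix, one named column per driver.
#' @param var_threshold Component retention threshold (default 0.85).
#' @param min_years Minimum complete years required (default 10 for the
#'   seven-driver model; below it the result is `NULL`, i.e. the pixel is
#'   missing in output maps).
#' @param sm Optional soil-moisture series enabling the Wind/SM term.
#' @return Object of class `wue_sensitivity` (`beta0`, `beta`,
#'   `interaction_beta`, `p_retained`, `r_squared`, `n_years`,
#'   `explained_cum`, `dropped`), or `NULL` when under-sampled.
#' @export
estimate_sensitivity <- function(y, X, var_threshold = 0.85, min_years = 10L,
                                 sm = NULL) {
  X <- as.matrix(X)
  ok <- is.finite(y) & apply(is.finite(X), 1L, all)
  if (!is.null(sm)) ok <- ok & is.finite(sm) & sm > 0
  if (sum(ok) < max(min_years, 3L)) return(NULL)
  y <- y[ok]
  X <- X[ok, , drop = FALSE]
  if (!is.null(sm)) {
    X <- cbind(X, wind_sm = X[, "wind"] / sm[ok])
  }
  design <- zscore_design(y, X)
  if (length(design$kept) == 0L) return(NULL)
  basis <- fit_components(design, threshold = var_threshold)
  reg <- pcr_regress(design, basis)
  bt <- backtransform(reg$beta_star, basis, design)
  beta <- bt$beta
  interaction_beta <- if ("wind_sm" %in% names(beta)) beta[["wind_sm"]] else NA_real_
  structure(
    list(beta0 = bt$beta0,
         beta = beta[setdiff(names(beta), "wind_sm")],
         interaction_beta = interaction_beta,
         p_retained = basis$p,
         explained_cum = sum(basis$explained_variance[seq_len(basis$p)]),
         r_squared = reg$r_squared,
         n_years = length(y),
         dropped = design$dropped),
    class = "wue_sensitivity"
  )
}

#' @export
print.wue_sensitivity <- function(x, ...) {
  cat(sprintf("<wue_sensitivity> n=%d, p=%d (%.1f%% var), R2=%.3f\n",
              x$n_years, x$p_retained, 100 * x$explained_cum, x$r_squared))
  print(round(x$beta, 5))
  if (is.finite(x$interaction_beta)) {
    cat(sprintf("  wind/SM interaction: %.5f\n", x$interaction_beta))
  }
  invisible(x)
}

#' Bootstrap (Monte Carlo) uncertainty of the wind sensitivity
#'
#' Resamples years with replacement, reruns the full PCR per replicate, and
#' summarizes the wind coefficient as relative uncertainty
#' (SD / |mean| over replicates) together with the mean R^2. A block
#' bootstrap (`block_length > 1`) is available for autocorrelated inputs.
#'
#' @inheritParams estimate_sensitivity
#' @param n_rep Number of replicates (default 1000).
#' @param seed Integer seed (required for reproducibility).
#' @param block_length Resampling block length in years (default 1, the
#'   plain case bootstrap).
#' @return List: `relative_uncertainty`, `mean_r2`, `sd`, `mean`,
#'   `n_effective` (replicates that produced a finite wind coefficient).
#' @export
monte_carlo_uncertainty <- function(y, X, n_rep = 1000L, seed = 1L,
                                    var_threshold = 0.85, min_years = 10L,
                                    sm = NULL, block_length = 1L) {
  full <- estimate_sensitivity(y, X, var_threshold, min_years, sm = sm)
  if (is.null(full)) {
    stop("sensitivity estimation failed on the full series", call. = FALSE)
  }
  n <- length(y)
  draw_idx <- function() {
    if (block_length <= 1L) return(sample.int(n, n, replace = TRUE))
    starts <- sample.int(n, ceiling(n / block_length), replace = TRUE)
    idx <- as.vector(outer(seq_len(block_length) - 1L, starts, "+"))
    ((idx - 1L) %% n) + 1L
  }
  with_seed(seed, {
    coefs <- rep(NA_real_, n_rep)
    r2 <- rep(NA_real_, n_rep)
    for (r in seq_len(n_rep)) {
      idx <- draw_idx()[seq_len(n)]
      fit <- suppressWarnings(
        tryCatch(estimate_sensitivity(y[idx], X[idx, , drop = FALSE],
                                      var_threshold, min_years,
                                      sm = if (is.null(sm)) NULL else sm[idx]),
                 error = function(e) NULL))
      if (!is.null(fit)) {
        coefs[r] <- fit$beta[["wind"]]
        r2[r] <- fit$r_squared
      }
    }
    m <- mean(coefs, na.rm = TRUE)
    s <- stats::sd(coefs, na.rm = TRUE)
    list(relative_uncertainty = if (abs(m) > 0) s / abs(m) else NA_real_,
         mean_r2 = mean(r2, na.rm = TRUE),
         sd = s, mean = m,
         n_effective = sum(is.finite(coefs)))
  })
}
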
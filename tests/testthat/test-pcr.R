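# PCR estimator: standardization round-trip, component retention, the
# back-transformation's equivalence with direct least squares, parameter
# recovery, interaction term, bootstrap uncertainty, ensemble averaging.

rand_instance <- function(n = 30, k = 7, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- matrix(rnorm(n * k), n, k, dimnames = list(NULL, paste0("x", 1:k)))
  y <- rnorm(n)
  list(y = y, X = X)
}

test_that("z-scoring standardizes, inverts exactly and flags degeneracy", {
  set.seed(1)
  d <- rand_instance(40)
  z <- zscore_design(d$y, d$X)
  expect_lt(max(abs(colMeans(z$x_star))), 1e-10)
  expect_lt(max(abs(apply(z$x_star, 2, sd) - 1)), 1e-10)
  # exact round trip
  back <- sweep(sweep(z$x_star, 2, z$xs[z$kept], "*"), 2, z$xm[z$kept], "+")
  expect_lt(max(abs(back - d$X)), 1e-12)
  expect_lt(max(abs(z$y_star * z$ys + z$ym - d$y)), 1e-12)
  # constant column (CO2 over a short window) is flagged, not zero-filled
  Xc <- cbind(d$X, co2 = 380)
  expect_warning(zc <- zscore_design(d$y, Xc), "zero-variance")
  expect_identical(zc$dropped, "co2")
  expect_false("co2" %in% colnames(zc$x_star))
})

test_that("component retention follows the strict >85% rule and the rank", {
  set.seed(2)
  # near-uncorrelated drivers: each component ~1/7, so six are needed
  d <- rand_instance(500)
  z <- zscore_design(d$y, d$X)
  b <- fit_components(z, threshold = 0.85)
  expect_equal(b$p, 6L)
  expect_lt(max(abs(crossprod(b$loadings) - diag(7))), 1e-10)
  expect_gt(sum(b$explained_variance[seq_len(b$p)]), 0.85)

  # two perfectly collinear drivers collapse into one component
  X2 <- d$X
  X2[, 2] <- 2 * X2[, 1] + 3
  z2 <- zscore_design(d$y, X2)
  b2 <- fit_components(z2, threshold = 1)
  expect_equal(b2$rank, 6L)
  expect_lte(b2$p, 6L)
  L1 <- b2$loadings[1:2, 1]
  expect_equal(unname(abs(L1[1])), unname(abs(L1[2])),
               tolerance = 1e-8) # paired loadings

  # a dominant first component is retained alone
  z3 <- zscore_design(d$y, cbind(a = d$X[, 1], b = d$X[, 1] + 1e-3 * d$X[, 2]))
  b3 <- fit_components(z3, threshold = 0.85)
  expect_equal(b3$p, 1L)
})

test_that("component-space regression matches its closed forms", {
  set.seed(3)
  d <- rand_instance(60)
  z <- zscore_design(d$y, d$X)
  b <- fit_components(z, threshold = 1)
  r <- pcr_regress(z, b)
  expect_lt(abs(r$beta0_star), 1e-10)
  # full rank: identical predictions to direct OLS of y* on x*
  ols_fit <- lm.fit(cbind(1, z$x_star), z$y_star)
  expect_lt(max(abs(r$fitted - ols_fit$fitted.values)), 1e-8)
  # single component: beta* = cov(y*, z1)/var(z1)
  b1 <- b; b1$p <- 1L
  r1 <- pcr_regress(z, b1)
  z1 <- drop(z$x_star %*% b$loadings[, 1])
  expect_equal(unname(r1$beta_star[1]), cov(z$y_star, z1) / var(z1),
               tolerance = 1e-10)
  # response orthogonal to every score -> all coefficients zero
  Q <- qr.Q(qr(cbind(1, z$x_star)), complete = TRUE)
  y_perp <- Q[, ncol(Q)]
  zp <- zscore_design(y_perp, d$X)
  rp <- pcr_regress(zp, fit_components(zp, threshold = 1))
  expect_lt(max(abs(rp$beta_star)), 1e-8)
})

test_that("full-retention back-transformation equals direct least squares (property)", {
  set.seed(4)
  worst <- 0
  for (r in 1:50) {
    d <- rand_instance(30)
    z <- zscore_design(d$y, d$X)
    b <- fit_components(z, threshold = 1)
    bt <- backtransform(pcr_regress(z, b)$beta_star, b, z)
    ols <- coef(lm(d$y ~ d$X))
    worst <- max(worst, abs(bt$beta0 - ols[1]), max(abs(bt$beta - ols[-1])))
  }
  expect_lt(worst, 1e-8)
})

test_that("back-transformation is invariant to the loading sign convention", {
  set.seed(5)
  d <- rand_instance(40)
  z <- zscore_design(d$y, d$X)
  b <- fit_components(z, threshold = 0.85)
  bt <- backtransform(pcr_regress(z, b)$beta_star, b, z)
  b_flipped <- b
  b_flipped$loadings <- -b$loadings
  bt2 <- backtransform(pcr_regress(z, b_flipped)$beta_star, b_flipped, z)
  expect_equal(bt$beta, bt2$beta, tolerance = 1e-10)
})

test_that("unit-scale case reduces the back-transformation to the loading sum", {
  # build columns with mean 0, sd exactly 1 so ys = xs_j = 1 paths are exact
  set.seed(6)
  X <- scale(matrix(rnorm(200), 50, 4))
  X <- sweep(X, 2, apply(X, 2, sd), "/")
  colnames(X) <- paste0("x", 1:4)
  y <- drop(scale(rnorm(50)))
  y <- y / sd(y)
  z <- zscore_design(y, X)
  b <- fit_components(z, threshold = 1)
  bs <- pcr_regress(z, b)$beta_star
  bt <- backtransform(bs, b, z)
  expect_equal(unname(bt$beta),
               unname(drop(b$loadings[, 1:b$p] %*% bs)), tolerance = 1e-10)
})

test_that("noise-free synthetic pixels recover the true sensitivities", {
  sp <- small_spec(noise_sd = 0, rng_seed = 81L)
  dr <- generate_drivers(sp)
  wue <- generate_wue(dr, sp)
  fit <- estimate_sensitivity(pixel_wue(wue, 3), pixel_design(dr, 3),
                              var_threshold = 1)
  expect_lt(max(abs(fit$beta - sp$true_beta)), 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
})

test_that("pixels with too few years are reported missing, not fitted", {
  d <- rand_instance(8, seed = 7)
  expect_null(estimate_sensitivity(d$y, d$X, min_years = 10))
})

test_that("rescaling a driver divides its coefficient by the factor exactly", {
  d <- rand_instance(35, seed = 8)
  f1 <- estimate_sensitivity(d$y, d$X, var_threshold = 0.85)
  X2 <- d$X
  X2[, "x1"] <- X2[, "x1"] * 100
  f2 <- estimate_sensitivity(d$y, X2, var_threshold = 0.85)
  expect_equal(f2$beta[["x1"]], f1$beta[["x1"]] / 100, tolerance = 1e-10)
})

test_that("shuffling the response yields wind coefficients centred on zero", {
  sp <- small_spec(rng_seed = 91L)
  dr <- generate_drivers(sp)
  wue <- generate_wue(dr, sp)
  y <- pixel_wue(wue, 2)
  X <- pixel_design(dr, 2)
  colnames(X) <- c("wind", "tair", "pressure", "precip", "swrad", "vpd", "co2")
  set.seed(9)
  coefs <- replicate(200, {
    estimate_sensitivity(sample(y), X)$beta[["wind"]]
  })
  expect_lt(abs(mean(coefs)) / sd(coefs) * sqrt(200), 3)
})

test_that("bootstrap uncertainty is seeded, reproducible and vanishes without noise", {
  sp <- small_spec(noise_sd = 0, rng_seed = 101L)
  dr <- generate_drivers(sp)
  wue <- generate_wue(dr, sp)
  y <- pixel_wue(wue)
  X <- pixel_design(dr)
  colnames(X) <- c("wind", "tair", "pressure", "precip", "swrad", "vpd", "co2")
  m1 <- monte_carlo_uncertainty(y, X, n_rep = 60, seed = 11, var_threshold = 1)
  m2 <- monte_carlo_uncertainty(y, X, n_rep = 60, seed = 11, var_threshold = 1)
  m3 <- monte_carlo_uncertainty(y, X, n_rep = 60, seed = 12, var_threshold = 1)
  expect_identical(m1, m2)
  expect_false(identical(m1$relative_uncertainty, m3$relative_uncertainty))
  expect_lt(m1$relative_uncertainty, 1e-8)
})

test_that("interaction estimation equals direct OLS with the ratio column at full rank", {
  sp <- synthetic_spec(grid_shape = c(2, 2), interaction_gamma = -0.02,
                       rng_seed = 111L)
  dr <- generate_drivers(sp)
  wue <- generate_wue(dr, sp)
  y <- pixel_wue(wue)
  X <- pixel_design(dr)
  colnames(X) <- c("wind", "tair", "pressure", "precip", "swrad", "vpd", "co2")
  sm <- pixel_sm(dr)
  fit <- estimate_sensitivity(y, X, var_threshold = 1, sm = sm)
  ols <- lm.fit(cbind(1, X, X[, "wind"] / sm), y)$coefficients
  expect_equal(unname(fit$interaction_beta), unname(ols[length(ols)]),
               tolerance = 1e-8)
  # noise-free: the interaction coefficient is the generating gamma
  sp0 <- synthetic_spec(grid_shape = c(2, 2), interaction_gamma = -0.02,
                        noise_sd = 0, rng_seed = 112L)
  dr0 <- generate_drivers(sp0)
  wue0 <- generate_wue(dr0, sp0)
  fit0 <- estimate_sensitivity(pixel_wue(wue0), pixel_design(dr0),
                               var_threshold = 1, sm = pixel_sm(dr0))
  expect_equal(unname(fit0$interaction_beta), -0.02, tolerance = 1e-8)
})

test_that("with no true interaction the recovered coefficients centre on zero", {
  sp <- synthetic_spec(grid_shape = c(6, 6), rng_seed = 113L)
  dr <- subset_years(generate_drivers(sp), c(1983, 2014))
  spn <- sp
  spn$noise_sd <- 0.03
  wue <- subset_years(generate_wue(generate_drivers(sp), spn), c(1983, 2014))
  # full retention: the unbiased case (component truncation shrinks
  # coefficients toward zero asymmetrically, so it is excluded here)
  sm <- sensitivity_grid(wue, dr, interaction = TRUE, var_threshold = 1)
  vals <- sm$interaction_beta[is.finite(sm$interaction_beta)]
  expect_lt(abs(mean(vals)) / (sd(vals) / sqrt(length(vals))), 4)
})

test_that("ensemble averaging is identity-preserving and missing-aware", {
  m <- matrix(c(-0.13, NA, -0.2, 0.1), 2, 2)
  expect_equal(ensemble_average(list(m, m, m)), m)
  expect_equal(ensemble_average(list(matrix(-0.13), matrix(-0.14),
                                     matrix(-0.10)))[1, 1],
               mean(c(-0.13, -0.14, -0.10)))
  a <- matrix(c(1, NA), 1, 2)
  b <- matrix(c(3, 5), 1, 2)
  expect_equal(ensemble_average(list(a, b)), matrix(c(2, 5), 1, 2))
})
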
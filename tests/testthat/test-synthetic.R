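# Synthetic-data generator: determinism, distributional convergence,
# ground-truth closure, and the built-in degenerate cases.

test_that("zero-noise wind equals the deterministic triphasic line at every pixel", {
  sp <- synthetic_spec(grid_shape = c(3, 3),
                       driver_sds = c(wind = 0, tair = 0, pressure = 0,
                                      precip = 0, swrad = 0, vpd = 0,
                                      co2 = 0, sm = 0))
  dr <- generate_drivers(sp)
  mu <- wind_trajectory(sp)
  w <- matrix(dr$wind$values, length(sp$years))
  for (px in seq_len(ncol(w))) expect_equal(w[, px], mu, tolerance = 1e-12)
})

test_that("segment-wise fitted trends reproduce the designed decadal magnitudes", {
  sp <- synthetic_spec(grid_shape = c(2, 2),
                       driver_sds = c(wind = 0, tair = 0, pressure = 0,
                                      precip = 0, swrad = 0, vpd = 0,
                                      co2 = 0, sm = 0))
  mu <- wind_trajectory(sp)
  ph <- partition_phases(mu, sp$years, sp$wind_breakpoints[1],
                         sp$wind_breakpoints[2])
  decadal <- vapply(ph, function(p) p$trend$slope_per_decade, numeric(1))
  # decline / recovery / decline, per decade
  expect_equal(unname(decadal), c(-0.072, 0.041, -0.010), tolerance = 0.02)
})

test_that("uncorrelated spec yields near-zero wind-pressure sample correlation", {
  C <- diag(8)
  dimnames(C) <- list(names(synthetic_spec()$driver_means),
                      names(synthetic_spec()$driver_means))
  sp <- synthetic_spec(grid_shape = c(10, 10), correlation = C,
                       rng_seed = 11L)
  dr <- generate_drivers(sp)
  # detrend against the mean trajectories so only the noise correlates
  w <- sweep(matrix(dr$wind$values, length(sp$years)), 1L,
             wind_trajectory(sp))
  p <- sweep(matrix(dr$pressure$values, length(sp$years)), 1L,
             sp$driver_means[["pressure"]] +
               sp$other_trends[["pressure"]] * (sp$years - mean(sp$years)))
  r <- cor(as.numeric(w), as.numeric(p)) # 11,800 pixel-years
  expect_lt(abs(r), 0.05)
})

test_that("empirical cross-correlations converge to the specified matrix", {
  sp <- synthetic_spec(grid_shape = c(8, 8), rng_seed = 21L)
  dr <- generate_drivers(sp)
  ny <- length(sp$years)
  mu <- windwue:::mean_trajectories(sp)
  eps <- sapply(names(dr), function(v)
    as.numeric(sweep(matrix(dr[[v]]$values, ny), 1L, mu[, v])))
  R <- cor(eps)
  expect_lt(max(abs(R - sp$correlation)), 0.05)
  # per-driver sample mean/SD within 3 standard errors. The conservative
  # effective sample size is the number of years: CO2 is one global series
  # and the other drivers share part of it, so pixel-years are not
  # independent draws.
  n_eff <- ny
  for (v in colnames(eps)) {
    sdv <- sp$driver_sds[[v]]
    expect_lt(abs(mean(eps[, v])), 3 * sdv / sqrt(n_eff) + 1e-12)
    if (sdv > 0) {
      expect_lt(abs(sd(eps[, v]) - sdv), 3 * sdv / sqrt(2 * (n_eff - 1)))
    }
  }
})

test_that("identical spec and seed give bit-identical output; seeds differ", {
  sp <- small_spec(rng_seed = 7L)
  d1 <- generate_drivers(sp)
  d2 <- generate_drivers(sp)
  expect_identical(d1, d2)
  w1 <- generate_wue(d1, sp)
  expect_identical(w1, generate_wue(d2, sp))
  d3 <- generate_drivers(small_spec(rng_seed = 8L))
  expect_false(identical(d1$wind$values, d3$wind$values))
})

test_that("non-PSD correlation matrices are rejected with a diagnostic", {
  C <- default_driver_correlation()
  C["wind", "tair"] <- C["tair", "wind"] <- 0.99
  C["wind", "vpd"] <- C["vpd", "wind"] <- 0.99
  C["tair", "vpd"] <- C["vpd", "tair"] <- -0.99
  expect_error(synthetic_spec(correlation = C), "positive semi-definite")
})

test_that("noise-free WUE is an exact linear function of the drivers", {
  sp <- small_spec(noise_sd = 0, rng_seed = 31L)
  dr <- generate_drivers(sp)
  wue <- generate_wue(dr, sp)
  y <- pixel_wue(wue, 5)
  X <- pixel_design(dr, 5)
  fit <- lm(y ~ X)
  expect_lt(max(abs(coef(fit)[-1] - sp$true_beta)), 1e-8)
})

test_that("hand-set drivers give hand-computed WUE", {
  dr <- hand_drivers()
  sp <- synthetic_spec(grid_shape = c(1, 1), years = c(2000, 2004),
                       wind_breakpoints = c(2001, 2003), noise_sd = 0)
  wue <- generate_wue(dr, sp)
  X <- pixel_design(dr)
  b0 <- windwue:::wue_intercept(sp)
  expect_equal(pixel_wue(wue), b0 + drop(X %*% sp$true_beta),
               tolerance = 1e-12)
})

test_that("a drier soil makes the wind term's marginal effect more negative", {
  sp <- synthetic_spec(grid_shape = c(1, 1), years = c(2000, 2004),
                       wind_breakpoints = c(2001, 2003),
                       interaction_gamma = -0.02, noise_sd = 0)
  # marginal dWUE/dWind at soil moisture sm is beta_wind + gamma / sm
  marg <- function(sm) sp$true_beta[["wind"]] + sp$interaction_gamma / sm
  expect_lt(marg(0.10), marg(0.20))
})

test_that("the Wind/SM term is rejected when soil moisture is not positive", {
  dr <- hand_drivers()
  dr$sm$values[2, 1, 1] <- -0.01
  sp <- synthetic_spec(grid_shape = c(1, 1), years = c(2000, 2004),
                       wind_breakpoints = c(2001, 2003),
                       interaction_gamma = -0.02, noise_sd = 0)
  expect_error(generate_wue(dr, sp), "strictly positive")
})

test_that("site tables carry the constructed degenerate cases", {
  sp <- small_spec(rng_seed = 41L)
  tab <- generate_site_table(sp, 1000, negligible_frac = 0.10,
                             negligible_et = 0.01)
  inj <- attr(tab, "injected")
  expect_length(inj$negligible, 100)
  expect_identical(which(tab$et < 0.05), inj$negligible)
  # clean table: nothing below the flux threshold
  tab2 <- generate_site_table(sp, 500)
  expect_true(all(tab2$et >= 0.05))
})

test_that("a synthetic station record passes the coverage screen", {
  sp <- small_spec()
  n <- as.integer(as.Date("2024-01-01") - as.Date("1983-01-01"))
  tab <- generate_site_table(sp, n, start_date = as.Date("1983-01-01"))
  sc <- screen_station(tab$date, period = c(1983, 2023))
  expect_true(sc$keep)
})

test_that("mask layers put exactly the stated fraction of pixels over threshold", {
  m0 <- generate_mask_layers(c(5, 5))
  expect_true(all(grassland_keep_mask(m0)))
  m <- generate_mask_layers(c(10, 10),
                            fractions = c(human_footprint = 0.2,
                                          burned_area = 0, cultivated = 0),
                            rng_seed = 3L)
  keep <- grassland_keep_mask(m)
  expect_identical(!keep, m$exceeds$human_footprint)
  expect_equal(sum(!keep), 20)
})

test_that("ground truth echoes the spec and freezes realized induced changes", {
  sp <- small_spec(rng_seed = 51L)
  dr <- generate_drivers(sp)
  tr <- synthetic_truth(sp, dr, period = c(1983, 2014))
  expect_identical(tr$beta_true, sp$true_beta)
  expect_identical(tr$breakpoints_true, sp$wind_breakpoints)
  # wind declines then partially recovers over 1983-2014: induced change
  # from a negative sensitivity must be positive
  expect_gt(tr$per_driver_induced_change[["wind"]], 0)
  expect_gt(tr$per_driver_induced_change[["co2"]], 0)
})
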
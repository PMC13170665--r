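# WUE ratio, the two-step site filter, station screening, Buck VPD,
# soil-layer averaging, disturbance masking and anomalies.

test_that("WUE is the exact GPP/ET ratio with guarded degenerate cells", {
  expect_equal(compute_wue(120, 60), 2.0)
  expect_true(is.na(compute_wue(120, 0)))    # never infinity
  expect_true(is.na(compute_wue(120, -1)))
  expect_true(is.na(compute_wue(NA, 60)))
})

test_that("gridded WUE rejects unit mismatches instead of guessing", {
  gpp <- gridded_field(array(120, c(2, 1, 1)), 1:2, 45, 10, "gpp",
                       "g C m-2")
  et_bad <- gridded_field(array(60, c(2, 1, 1)), 1:2, 45, 10, "et", "W m-2")
  expect_error(compute_wue(gpp, et_bad), "units")
  et <- gridded_field(array(60, c(2, 1, 1)), 1:2, 45, 10, "et", "mm")
  expect_equal(as.numeric(compute_wue(gpp, et)$values), c(2, 2))
})

test_that("annual WUE is the ratio of sums, which differs from the mean of ratios", {
  # two months: high-flux efficient month, low-flux inefficient month
  gpp <- c(100, 1)
  et <- c(40, 10)
  yr <- c(2000, 2000)
  rs <- annual_wue(gpp, et, yr)$wue
  expect_equal(rs, 101 / 50)
  expect_false(isTRUE(all.equal(rs, mean(gpp / et))))
})

test_that("two-step filter removes negligible-flux days first, then the WUE tail", {
  sp <- small_spec(rng_seed = 61L)
  tab <- generate_site_table(sp, 1000, negligible_frac = 0.01,
                             negligible_et = 0.02)
  res <- filter_site_records(tab)
  expect_equal(res$report$n_removed_et, 10)
  # brute-force percentile oracle on the step-1 survivors
  surv <- tab[tab$et >= 0.05, ]
  wue <- surv$gpp / surv$et
  q99 <- quantile(wue, 0.99, names = FALSE, type = 7)
  expect_equal(res$report$n_removed_wue, sum(wue > q99))
  expect_equal(res$report$n_kept, nrow(tab) - res$report$n_removed_et -
                 res$report$n_removed_wue)
  # survivors all at or below the threshold
  expect_true(all(res$table$wue <= q99))
})

test_that("filter order matters: percentile after the flux screen differs from before", {
  # adversarial: the low-ET days carry enormous WUE, so a percentile taken
  # before the flux screen sits far above every legitimate record and the
  # outlier step then removes nothing
  tab <- data.frame(site_id = "A",
                    gpp = c(1:90, rep(10, 10)),
                    et = c(rep(1, 90), rep(0.01, 10)))
  correct <- filter_site_records(tab)
  expect_equal(correct$report$n_removed_et, 10)
  expect_equal(correct$report$n_removed_wue, 1) # top of the 1..90 ladder
  # swapped ordering, done by hand
  wue_all <- tab$gpp / tab$et
  q99_all <- quantile(wue_all, 0.99, names = FALSE, type = 7)
  swapped_keep <- tab[wue_all <= q99_all & tab$et >= 0.05, ]
  expect_equal(nrow(swapped_keep), 90)
  expect_false(nrow(correct$table) == nrow(swapped_keep))
})

test_that("empty tables filter to empty output with a zero report", {
  res <- filter_site_records(data.frame(gpp = numeric(), et = numeric()))
  expect_equal(res$report$n_input, 0L)
  expect_equal(nrow(res$table), 0L)
})

test_that("station screening enforces coverage, completeness and valid-day minima", {
  dates <- seq(as.Date("1983-01-01"), as.Date("2023-12-31"), by = "day")
  ok <- screen_station(dates)
  expect_true(ok$keep)

  # one month with only 14 valid days
  valid <- rep(TRUE, length(dates))
  jan90 <- which(format(dates, "%Y-%m") == "1990-01")
  valid[jan90[15:length(jan90)]] <- FALSE
  bad <- screen_station(dates, valid)
  expect_false(bad$keep)
  expect_match(bad$reason, "below minimum valid days")

  # a year missing December entirely
  dates2 <- dates[format(dates, "%Y-%m") != "2000-12"]
  bad2 <- screen_station(dates2)
  expect_false(bad2$keep)
  expect_match(bad2$reason, "missing calendar month")
})

test_that("Buck VPD matches an independent transcription and its limits", {
  expect_equal(buck_vpd(20, 101.325, 100), 0)
  # independent constants, transcribed separately from the implementation
  es_oracle <- function(t, p_kpa) {
    (1.0007 + 3.46e-6 * (p_kpa * 10)) * 0.61121 * exp(17.502 * t / (240.97 + t))
  }
  expect_equal(buck_vpd(20, 101.325, 50), es_oracle(20, 101.325) * 0.5,
               tolerance = 1e-6)
  # monotone in temperature below saturation
  v <- buck_vpd(seq(-5, 40, by = 5), 95, 60)
  expect_true(all(diff(v) > 0))
  expect_error(buck_vpd(20, 100, 105), "\\[0, 100\\]")
})

test_that("soil-moisture averaging weights layers by clipped thickness", {
  expect_equal(sm_weighted_mean(c(0.30, 0.20), rbind(c(0, 10), c(10, 28))),
               (10 * 0.30 + 18 * 0.20) / 28)
  expect_equal(sm_weighted_mean(0.25, rbind(c(0, 28))), 0.25)
  # a 20-40 cm layer contributes only its 8 cm of overlap
  expect_equal(sm_weighted_mean(c(0.3, 0.1), rbind(c(0, 20), c(20, 40))),
               (20 * 0.3 + 8 * 0.1) / 28)
  expect_true(is.na(sm_weighted_mean(0.3, rbind(c(30, 50)))))
  expect_error(sm_weighted_mean(c(0.3, 0.1), rbind(c(0, 15), c(10, 28))),
               "non-overlapping")
})

test_that("disturbance thresholds are strict and masking is idempotent", {
  m <- generate_mask_layers(c(2, 2))
  m$human_footprint[1, 1] <- 0.51   # just over 50% -> excluded
  m$burned_area[2, 1] <- 0.30       # exactly 30% -> retained
  m$cultivated[1, 2] <- 0.31        # just over -> excluded
  keep <- grassland_keep_mask(m)
  expect_identical(as.vector(keep), c(FALSE, TRUE, FALSE, TRUE))

  sp <- synthetic_spec(grid_shape = c(2, 2), years = c(1983, 1990),
                       wind_breakpoints = c(1985, 1987))
  dr <- generate_drivers(sp)
  masked <- apply_grassland_mask(dr, m)
  expect_true(all(is.na(masked$wind$values[, 1, 1])))
  expect_identical(apply_grassland_mask(masked, m), masked)
})

test_that("anomalies centre each pixel and reproduce the percent-per-decade convention", {
  sp <- small_spec(rng_seed = 71L)
  dr <- generate_drivers(sp)
  an <- anomaly(dr$wind)
  m <- matrix(an$values, length(sp$years))
  expect_lt(max(abs(colMeans(m))), 1e-10)

  cf <- gridded_field(array(5, c(4, 2, 2)), 1:4, c(40, 50), c(0, 10),
                      "x", "m s-1")
  expect_true(all(anomaly(cf)$values == 0))
  expect_error(anomaly(cf, baseline = c(10, 20)), "baseline")

  # -0.072 m/s per decade on a 3.35 m/s baseline is -2.15% per decade
  tr <- linear_trend(3.35 - 0.0072 * (0:27), 1983:2010, baseline_mean = 3.35)
  expect_equal(tr$percent_per_decade, -2.149, tolerance = 1e-3)
})
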
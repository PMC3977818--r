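test_that("nucleus/cytoplasm ratios behave as ratios", {
  times <- seq(0, 2, by = 0.1)
  n <- length(times)
  counts <- cbind(nuc = rep(50, n), cyt = rep(50, n), extra = rep(25, n))
  tr <- structure(list(times = times, counts = counts, mode = "ode"),
                  class = "iir_trajectory")
  expect_equal(nc_ratio(tr, "nuc", "cyt")$values, rep(1, n))
  counts2 <- cbind(nuc = rep(100, n), cyt = rep(50, n))
  tr2 <- structure(list(times = times, counts = counts2, mode = "ode"),
                   class = "iir_trajectory")
  expect_equal(nc_ratio(tr2, "nuc", "cyt")$values, rep(2, n))
  # volume correction multiplies by the cytoplasm/nucleus volume ratio
  expect_equal(nc_ratio(tr2, "nuc", "cyt", volume_corrected = TRUE)$values,
               rep(10, n))
  # zero cytoplasm errors unless floored
  counts3 <- cbind(nuc = rep(1, n), cyt = rep(0, n))
  tr3 <- structure(list(times = times, counts = counts3, mode = "ode"),
                   class = "iir_trajectory")
  expect_error(nc_ratio(tr3, "nuc", "cyt", eps_floor = 0), "zero")
  expect_true(all(is.finite(nc_ratio(tr3, "nuc", "cyt")$values)))
})

test_that("ratio series validate their grid and round-trip through CSV", {
  expect_error(ratio_series(c(0, 1, 3), c(1, 1, 1)), "uniform")
  rs <- ratio_series(seq(0, 1, by = 0.1), seq(1, 2, length.out = 11))
  path <- withr::local_tempfile(fileext = ".csv")
  write_ratio_series(rs, path)
  rs2 <- read_ratio_series(path)
  expect_equal(rs2$times, rs$times)
  expect_equal(rs2$values, rs$values)
})

test_that("cubic detrending removes exactly cubic structure", {
  t <- seq(0, 12, by = 0.1)
  cubic <- 2 + 0.5 * t - 0.08 * t^2 + 0.003 * t^3
  rs <- ratio_series(t, cubic)
  dt <- detrend_poly3(rs)
  expect_lt(max(abs(dt$detrended$values)), 1e-9)
  expect_equal(unname(dt$coefficients),
               c(2, 0.5, -0.08, 0.003), tolerance = 1e-6)
  # constant series: zero residuals
  dt2 <- detrend_poly3(ratio_series(t, rep(3, length(t))))
  expect_lt(max(abs(dt2$detrended$values)), 1e-12)
  expect_error(detrend_poly3(ratio_series(0:3, c(1, 2, 3, 4))), "at least 5")
})

test_that("detrending recovers an injected tone and is idempotent", {
  t <- seq(0, 12, by = 0.1)
  tone <- 0.4 * sin(2 * pi * t / 2)
  y <- (1 + 0.2 * t - 0.01 * t^2 + 0.0005 * t^3) + tone
  dt <- detrend_poly3(ratio_series(t, y))
  # amplitude of the recovered component within 5%
  amp <- sqrt(2 * mean(dt$detrended$values^2))
  expect_equal(amp, 0.4, tolerance = 0.05)
  dt2 <- detrend_poly3(dt$detrended)
  expect_equal(dt2$detrended$values, dt$detrended$values, tolerance = 1e-8)
})

test_that("periodogram nails a Fourier-aligned tone and conserves power", {
  t <- seq(0, 12 - 0.1, by = 0.1)  # n = 120, 6-min cadence
  y <- sin(2 * pi * t / 2)         # 2-hr tone, exactly bin 6
  pg <- periodogram(ratio_series(t, y))
  expect_equal(pg$dominant_period, 2)
  expect_gt(max(pg$power) / pg$total_power, 0.999)
  # Parseval at the stated normalization
  expect_equal(pg$total_power, sum((y - mean(y))^2), tolerance = 1e-8)
  # agreement with the classical periodogram (independent implementation)
  sp <- stats::spec.pgram(stats::ts(y, deltat = 0.1), taper = 0, fast = FALSE,
                          detrend = FALSE, demean = TRUE, plot = FALSE)
  expect_equal(pg$frequencies, as.numeric(sp$freq))
  expect_equal(pg$power / pg$total_power,
               as.numeric(sp$spec) / sum(sp$spec), tolerance = 1e-8)
})

test_that("white noise spreads power across bins", {
  t <- seq(0, 12 - 0.1, by = 0.1)
  set.seed(99)
  worst <- replicate(20, {
    pg <- periodogram(ratio_series(t, rnorm(length(t))))
    max(pg$power) / pg$total_power
  })
  expect_true(all(worst < 0.5))
})

test_that("dominant-period selection respects power and the search band", {
  t <- seq(0, 12 - 0.1, by = 0.1)
  y1 <- sin(2 * pi * t / 3)   # bin 4
  y2 <- sin(2 * pi * t / 1.5) # bin 8
  pg <- periodogram(ratio_series(t, 1.01 * y1 + y2))
  expect_equal(pg$dominant_period, 3)
  pg1 <- periodogram(ratio_series(t, y1 + 1.01 * y2))
  expect_equal(pg1$dominant_period, 1.5)
  # band restriction: excluding >2 hr picks the faster tone regardless
  pg2 <- periodogram(ratio_series(t, 1.01 * y1 + y2), band = c(0.5, 2))
  expect_equal(pg2$dominant_period, 1.5)
  # a band holding no Fourier period: NA
  pg3 <- periodogram(ratio_series(t, y1), band = c(20, 30))
  expect_true(is.na(pg3$dominant_period))
})
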
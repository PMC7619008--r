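# Build a spatial_profile object directly, bypassing the fit, for tests of
# the extraction stage alone.
manual_profile <- function(centers, sigmas, positions) {
  comp <- data.frame(center = centers, sigma = sigmas,
                     amplitude = NA_real_)
  comp$fwhm <- 2 * comp$sigma * sqrt(2 * log(2))
  comp$excluded <- comp$fwhm >= 1.5
  structure(list(components = comp, offset = 0, residual_rms = 0,
                 n_components = nrow(comp), positions = positions),
            class = "spatial_profile")
}

test_that("a noiseless single Gaussian is recovered within 1%", {
  truth <- quantal_series(numeric(0), integer(0), quantal_amplitude = 0.5)
  attr(truth, "duration") <- 0.3
  im <- imaging_model(n_positions = 32, pixel_size = 0.25, source_centers = 4,
                      source_widths = 0.4, noise_sd = 0, bleach_slope = 0)
  rec <- render_linescan(truth, glu_kernel(), im, seed = 1)
  prof <- fit_spatial_profile(rec)
  expect_equal(prof$n_components, 1L)
  expect_equal(prof$components$center, 4, tolerance = 0.01)
  expect_equal(prof$components$sigma, 0.4, tolerance = 0.01)
  expect_false(prof$components$excluded)
})

test_that("two separated sources are both recovered and one component is rejected", {
  truth <- quantal_series(numeric(0), integer(0), quantal_amplitude = 0.5)
  attr(truth, "duration") <- 0.3
  im <- imaging_model(n_positions = 40, pixel_size = 0.25,
                      source_centers = c(3, 5), source_widths = c(0.4, 0.4),
                      noise_sd = 0.002, bleach_slope = 0)
  rec <- render_linescan(truth, glu_kernel(), im, seed = 2)
  prof <- fit_spatial_profile(rec, max_components = 3)
  expect_equal(prof$n_components, 2L)
  expect_equal(prof$components$center, c(3, 5), tolerance = 0.05)
  # grid-search oracle: the best single Gaussian leaves far larger residual
  x <- rec$positions; y <- rowMeans(rec$values)
  rss1 <- min(vapply(seq(2, 6, by = 0.1), function(c0) {
    fit <- minpack.lm::nlsLM(y ~ b + a * exp(-(x - c0)^2 / (2 * s0^2)),
                             data = data.frame(x = x, y = y),
                             start = list(b = 0, a = max(y), s0 = 0.8),
                             control = minpack.lm::nls.lm.control(maxiter = 200))
    sum(stats::residuals(fit)^2)
  }, numeric(1)))
  expect_gt(sqrt(rss1 / length(y)), 5 * prof$residual_rms)
})

test_that("broad components are flagged by the width criterion", {
  # sigma 0.68 um -> FWHM 1.6 um: excluded; sigma 0.4 -> FWHM 0.94: kept
  truth <- quantal_series(numeric(0), integer(0), quantal_amplitude = 0.5)
  attr(truth, "duration") <- 0.3
  im <- imaging_model(n_positions = 48, pixel_size = 0.25,
                      source_centers = c(3, 8),
                      source_widths = c(0.4, 1.6 / (2 * sqrt(2 * log(2)))),
                      noise_sd = 0, bleach_slope = 0)
  rec <- render_linescan(truth, glu_kernel(), im, seed = 1)
  prof <- fit_spatial_profile(rec, max_components = 2)
  expect_equal(prof$n_components, 2L)
  expect_identical(prof$components$excluded, c(FALSE, TRUE))
  expect_equal(prof$components$fwhm[2], 1.6, tolerance = 0.02)
})

test_that("time-series extraction solves the per-timepoint least squares exactly", {
  x <- seq(0, 7.75, by = 0.25)
  g <- exp(-(x - 4)^2 / (2 * 0.4^2))
  gt <- 100 * (1 + 0.3 * sin(seq(0, 4 * pi, length.out = 400)))
  rec <- structure(list(values = outer(g, gt), line_rate = 1000,
                        pixel_size = 0.25, duration = 0.4, positions = x),
                   class = "linescan_recording")
  prof <- manual_profile(4, 0.4, x)
  tr <- extract_timeseries(rec, prof, include_offset = FALSE)
  expect_equal(tr[[1]]$f, gt, tolerance = 1e-9)

  # all-zero recording gives an all-zero series
  rec0 <- rec; rec0$values <- rec$values * 0
  tr0 <- extract_timeseries(rec0, prof, include_offset = FALSE)
  expect_true(all(abs(tr0[[1]]$f) < 1e-12))
})

test_that("two known time courses are demixed within the noise floor", {
  x <- seq(0, 9.75, by = 0.25)
  g1 <- exp(-(x - 3)^2 / (2 * 0.4^2))
  g2 <- exp(-(x - 6)^2 / (2 * 0.4^2))
  t1 <- 100 + 20 * sin(seq(0, 6 * pi, length.out = 300))
  t2 <- 80 + 15 * cos(seq(0, 3 * pi, length.out = 300))
  set.seed(42)
  vals <- outer(g1, t1) + outer(g2, t2) +
    matrix(rnorm(length(x) * 300, 0, 0.5), length(x))
  rec <- structure(list(values = vals, line_rate = 1000, pixel_size = 0.25,
                        duration = 0.3, positions = x),
                   class = "linescan_recording")
  tr <- extract_timeseries(rec, manual_profile(c(3, 6), c(0.4, 0.4), x),
                           include_offset = FALSE)
  expect_lt(sqrt(mean((tr[[1]]$f - t1)^2)), 1)
  expect_lt(sqrt(mean((tr[[2]]$f - t2)^2)), 1)
})

test_that("nearly collinear components are refused by name", {
  x <- seq(0, 7.75, by = 0.25)
  rec <- structure(list(values = matrix(1, length(x), 50), line_rate = 1000,
                        pixel_size = 0.25, duration = 0.05, positions = x),
                   class = "linescan_recording")
  prof <- manual_profile(c(4, 4.001), c(0.4, 0.4), x)
  expect_error(extract_timeseries(rec, prof), "collinear")
})
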
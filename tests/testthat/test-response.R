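test_that("cycle counting: vesicles, events, mean amplitude, unit conversion", {
  p <- make_stimulus(60, repeats = 1, randomize = FALSE)
  s <- quantal_series(c(0.03, 0.12), c(1L, 2L))
  cc <- count_per_cycle(s, p)
  expect_equal(cc$events, 2L)
  expect_equal(cc$vesicles, 3L)
  expect_equal(cc$mean_amplitude, 1.5)

  # 2.5 vesicles per cycle at 5 Hz is a release rate of 12.5 vesicles/s
  p2 <- make_stimulus(60, repeats = 4, randomize = FALSE)
  s2 <- quantal_series(c(0.1, 0.3, 0.5, 0.7), c(2L, 3L, 2L, 3L))
  rr <- release_rate_per_contrast(count_per_cycle(s2, p2))
  expect_equal(rr$mean_vesicles, 2.5)
  expect_equal(rr$rate, 12.5)

  # empty series: all cycles zero
  cc0 <- count_per_cycle(quantal_series(numeric(0), integer(0)), p2)
  expect_true(all(cc0$vesicles == 0))
  expect_true(all(is.na(cc0$mean_amplitude)))

  # events beyond the protocol are orphans
  expect_error(count_per_cycle(quantal_series(c(0.1, 0.9), c(1L, 1L)), p),
               "0.9")
})

test_that("cycle assignment uses half-open intervals", {
  p <- make_stimulus(c(20, 40), repeats = 1, randomize = FALSE)
  s <- quantal_series(c(0, 0.2), c(1L, 1L))   # exactly on the boundaries
  cc <- count_per_cycle(s, p)
  expect_equal(cc$events, c(1L, 1L))
})

test_that("Hill fits recover noiseless parameters and flag decreasing data", {
  contrasts <- seq(5, 100, by = 5)
  hill <- function(c, rmax, ch, n) rmax * c^n / (c^n + ch^n)
  df <- data.frame(contrast = contrasts,
                   mean_vesicles = hill(contrasts, 3, 50, 2))
  fit <- fit_hill(df)
  expect_equal(fit$r_max, 3, tolerance = 1e-3)
  expect_equal(fit$c_half, 50, tolerance = 1e-3)
  expect_equal(fit$hill_n, 2, tolerance = 1e-3)
  expect_false(fit$flagged)

  dec <- data.frame(contrast = contrasts,
                    mean_vesicles = rev(hill(contrasts, 3, 50, 2)))
  expect_true(fit_hill(dec)$flagged)

  expect_error(fit_hill(df[1:3, ]), "4 distinct")
})

test_that("Hill c_half recovery from Poisson counts is nearly unbiased", {
  contrasts <- seq(10, 100, length.out = 11)
  hill <- function(c) 3 * c^2 / (c^2 + 40^2)
  est <- vapply(1:100, function(s) {
    set.seed(s)
    mv <- vapply(contrasts, function(cc) mean(rpois(30, hill(cc))), numeric(1))
    fit_hill(data.frame(contrast = contrasts, mean_vesicles = mv))$c_half
  }, numeric(1))
  expect_lt(abs(stats::median(est) - 40) / 40, 0.05)
})

test_that("contrast gain is the OLS slope of normalized rates in the C1/2 window", {
  # construct exact linear relative rates with slope 0.05 per % contrast:
  # vesicle counts 10, 11, ..., 20 at 1 Hz so rate == vesicles per cycle
  contrasts <- seq(30, 50, 2)
  rates <- 10 * (1 + 0.05 * (contrasts - 30))     # integers 10..20
  counts <- structure(
    data.frame(cycle = seq_along(contrasts), contrast = contrasts,
               events = as.integer(rates), vesicles = as.integer(rates),
               mean_amplitude = 1),
    class = c("cyclewise_counts", "data.frame"), frequency = 1)
  g <- contrast_gain(counts, c_half = 40)
  expect_equal(g$slope, 0.05, tolerance = 1e-9)
  expect_equal(g$window, c(30, 50))
  expect_equal(g$normalization_contrast, 30)

  # flat rates give zero slope
  flat <- counts; flat$vesicles <- 10L; flat$events <- 10L
  expect_equal(contrast_gain(flat, 40)$slope, 0, tolerance = 1e-12)

  expect_error(contrast_gain(counts, c_half = 90), "window")
})

test_that("the rate x amplitude factorization identity holds by construction", {
  p <- standard_protocol(repeats = 6, seed = 2)
  m <- standard_model(mvr = c(0.4, 0.4, 0.2))
  s <- simulate_release(p, m, seed = 5)
  fc <- factorize_code(count_per_cycle(s, p))
  ok <- !is.na(fc$mean_amplitude)
  expect_equal(fc$vesicle_rate[ok], (fc$event_rate * fc$mean_amplitude)[ok],
               tolerance = 1e-12)
  # univesicular release: amplitude 1 everywhere, vesicle rate = event rate
  s1 <- simulate_release(p, standard_model(mvr = 1), seed = 5)
  fc1 <- factorize_code(count_per_cycle(s1, p))
  ok1 <- !is.na(fc1$mean_amplitude)
  expect_true(all(fc1$mean_amplitude[ok1] == 1))
  expect_equal(fc1$vesicle_rate[ok1], fc1$event_rate[ok1])
})

test_that("gain carried purely by amplitude shows up in the amplitude factor", {
  # event rate fixed; MVR shifts from 1 quantum to 2 quanta with contrast
  p <- make_stimulus(c(20, 80), repeats = 10, randomize = FALSE)
  times <- c(); quanta <- c()
  for (cyc in 0:19) {
    t0 <- cyc * 0.2
    times <- c(times, t0 + c(0.05, 0.15))
    quanta <- c(quanta, if (cyc < 10) c(1L, 1L) else c(2L, 2L))
  }
  s <- quantal_series(times, quanta)
  fc <- factorize_code(count_per_cycle(s, p))
  expect_equal(fc$relative_event_rate, c(1, 1))
  expect_equal(fc$relative_amplitude, c(1, 2))
  expect_equal(fc$relative_vesicle_rate, c(1, 2))
})

test_that("the factorization tracks a known contrast dependence of rate and amplitude", {
  p <- standard_protocol(repeats = 200, seed = 8)
  m <- standard_model(mvr = c(0.3, 0.5, 0.2))
  s <- simulate_release(p, m, seed = 21)
  fc <- factorize_code(count_per_cycle(s, p))
  truth_rate <- release_rate(m, fc$contrast)
  expect_gt(stats::cor(fc$event_rate, truth_rate), 0.9)
  mean_q <- sum(1:3 * c(0.3, 0.5, 0.2))
  ok <- !is.na(fc$mean_amplitude)
  expect_equal(mean(fc$mean_amplitude[ok]), mean_q, tolerance = 0.15)
})

test_that("amplitude distributions include the no-response class and sum to 1", {
  p <- make_stimulus(60, repeats = 10, randomize = FALSE)
  # 4 empty cycles, 6 cycles with one univesicular event each
  times <- (0:5) * 0.2 + 0.1
  s <- quantal_series(times, rep(1L, 6))
  d <- amplitude_distribution(count_per_cycle(s, p), series = s)
  expect_equal(d$probability[d$class == "no_response"], 0.4)
  expect_equal(d$probability[d$class == "1"], 0.6)
  expect_equal(sum(d$probability), 1)

  set.seed(1)
  s2 <- simulate_release(standard_protocol(), standard_model(), seed = 2)
  d2 <- amplitude_distribution(count_per_cycle(s2, standard_protocol()),
                               series = s2)
  expect_equal(sum(d2$probability), 1, tolerance = 1e-12)
})

test_that("chi-squared comparison of identical generators is calibrated", {
  p <- make_stimulus(c(30, 50), repeats = 25, seed = 1)
  m <- standard_model(mvr = c(0.6, 0.4))
  pvals <- vapply(1:200, function(s) {
    s1 <- simulate_release(p, m, seed = s)
    s2 <- simulate_release(p, m, seed = s + 10000)
    d1 <- amplitude_distribution(count_per_cycle(s1, p), series = s1)
    d2 <- amplitude_distribution(count_per_cycle(s2, p), series = s2)
    suppressMessages(compare_amplitude_distributions(d1, d2)$p.value)
  }, numeric(1))
  # under the null the p-values are approximately uniform
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("frequency responses are classified low-pass or band-pass with a margin", {
  lp <- data.frame(frequency = c(2, 5, 10, 20), rate = c(12, 9, 5, 2))
  expect_equal(frequency_response(lp)$classification, "low-pass")

  bp <- data.frame(frequency = c(2, 5, 10, 20), rate = c(6, 7, 9, 6))
  expect_equal(frequency_response(bp)$classification, "band-pass")

  # interior peak below the 20% margin stays low-pass
  weak <- data.frame(frequency = c(2, 5, 10), rate = c(10, 11, 10))
  expect_equal(frequency_response(weak)$classification, "low-pass")

  # identical condition and reference: unit relative gain everywhere
  fr <- frequency_response(lp, reference = lp)
  expect_true(all(fr$table$relative_gain == 1))

  expect_error(frequency_response(lp[1:2, ]), "3 frequencies")
})

test_that("per-contrast measures are invariant to translating series and protocol together", {
  p <- standard_protocol(repeats = 10, seed = 3)
  m <- standard_model()
  s <- simulate_release(p, m, seed = 4)
  # translate everything by two whole cycles: rotate the contrast sequence and
  # shift the event times correspondingly (wrapping the tail to the front)
  k <- 2L; dt <- k * p$cycle_duration
  p2 <- p
  p2$contrasts <- c(utils::tail(p$contrasts, -k), utils::head(p$contrasts, k))
  wrapped <- s$times - dt
  wrapped[wrapped < 0] <- wrapped[wrapped < 0] + p$duration
  ord <- order(wrapped)
  s2 <- quantal_series(wrapped[ord], s$quanta[ord])
  fc1 <- factorize_code(count_per_cycle(s, p))
  fc2 <- factorize_code(count_per_cycle(s2, p2))
  expect_equal(fc1, fc2, tolerance = 1e-12)
})
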
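#' Ground-truth release model for the simulator
#'
#' Describes how a model synapse converts stimulus contrast into glutamate
#' release: a per-cycle event rate (linear or Hill-saturating in contrast) and
#' a multivesicular-release (MVR) mixture giving the probability that a single
#' release event comprises 1, 2, 3, ... synchronously fused vesicles.
#'
#' The rate function is
#' `rate(c) = base_rate + rate_gain * c` when no Hill parameters are given, or
#' `rate(c) = base_rate + r_max * c^hill_n / (c^hill_n + c_half^hill_n)`
#' when `r_max`, `c_half` and `hill_n` are supplied.
#'
#' @param base_rate events per second at zero contrast (spontaneous rate).
#' @param rate_gain events per second per percent contrast (linear mode).
#' @param r_max,c_half,hill_n Hill-mode parameters: maximal evoked event rate
#'   (events/s), half-maximal contrast (%), Hill exponent. Supply all three or
#'   none.
#' @param quantal_amplitude peak dF/F0 of a single vesicle's transient.
#' @param mvr_weights probability vector over quanta-per-event 1, 2, 3, ...;
#'   must sum to 1.
#' @param amplitude_cv fractional spread of a single quantum's amplitude.
#' @return a `release_model` object.
#' @export
release_model <- function(base_rate = 0, rate_gain = 0,
                          r_max = NULL, c_half = NULL, hill_n = NULL,
                          quantal_amplitude = 0.5,
                          mvr_weights = c(1), amplitude_cv = 0) {
  stopifnot(base_rate >= 0, rate_gain >= 0, amplitude_cv >= 0,
            quantal_amplitude > 0, all(mvr_weights >= 0))
  if (abs(sum(mvr_weights) - 1) > 1e-9)
    stop("mvr_weights must sum to 1")
  hill <- !is.null(r_max)
  if (hill) {
    stopifnot(!is.null(c_half), !is.null(hill_n),
              r_max >= 0, c_half > 0, hill_n > 0)
  }
  structure(list(base_rate = base_rate, rate_gain = rate_gain,
                 r_max = r_max, c_half = c_half, hill_n = hill_n,
                 hill = hill,
                 quantal_amplitude = quantal_amplitude,
                 mvr_weights = mvr_weights / sum(mvr_weights),
                 amplitude_cv = amplitude_cv),
            class = "release_model")
}

#' Event rate of a release model at given contrasts
#' @param model a [release_model()].
#' @param contrast percent contrast (vector).
#' @return events per second at each contrast.
#' @export
release_rate <- function(model, contrast) {
  stopifnot(inherits(model, "release_model"))
  if (model$hill) {
    cn <- contrast ^ model$hill_n
    model$base_rate + model$r_max * cn / (cn + model$c_half ^ model$hill_n)
  } else {
    model$base_rate + model$rate_gain * contrast
  }
}

#' Construct a quantal event series
#'
#' The central event container: release times paired with integer vesicle
#' counts (quanta) per event.
#'
#' @param times event times in seconds, strictly increasing.
#' @param quanta positive integers, vesicles per event; same length as `times`.
#' @param quantal_amplitude dF/F0 per vesicle, if known (NA otherwise).
#' @param polarity `"ON"`, `"OFF"` or `"unknown"`.
#' @return a `quantal_series` object.
#' @export
quantal_series <- function(times, quanta,
                           quantal_amplitude = NA_real_,
                           polarity = "unknown") {
  stopifnot(length(times) == length(quanta))
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("event times must be strictly increasing")
  quanta <- as.integer(quanta)
  if (length(quanta) && any(quanta < 1L))
    stop("quanta must be >= 1")
  polarity <- match.arg(polarity, c("ON", "OFF", "unknown"))
  structure(list(times = as.numeric(times), quanta = quanta,
                 quantal_amplitude = quantal_amplitude,
                 polarity = polarity),
            class = "quantal_series")
}

#' @export
print.quantal_series <- function(x, ...) {
  cat(sprintf("Quantal series: %d events, %d vesicles, polarity %s\n",
              length(x$times), sum(x$quanta), x$polarity))
  invisible(x)
}

#' Simulate ground-truth quantal release under a stimulus protocol
#'
#' Draws release events cycle by cycle: the number of events in a cycle is
#' Poisson with mean `cycle_duration * rate(contrast)`, event times are placed
#' within the cycle either uniformly (homogeneous Poisson, the default) or
#' clustered at a preferred stimulus phase, and each event's vesicle count is
#' drawn from the model's MVR mixture.
#'
#' @param protocol a [make_stimulus()] protocol.
#' @param model a [release_model()].
#' @param seed integer seed; identical (inputs, seed) give identical output.
#' @param phase_lock if `TRUE`, event phases within a cycle are drawn from a
#'   truncated Gaussian centred at `phase_mean` (fraction of cycle) with
#'   spread `phase_sd`, emulating release locked to one stimulus phase.
#' @param phase_mean,phase_sd phase-locking parameters (fractions of a cycle).
#' @param min_separation optional minimum separation in seconds; events closer
#'   than this to their predecessor are discarded (thinning), useful for
#'   generating well-isolated transients.
#' @return a [quantal_series()] with the model's quantal amplitude attached.
#' @export
simulate_release <- function(protocol, model, seed = 1L,
                             phase_lock = FALSE, phase_mean = 0.25,
                             phase_sd = 0.08, min_separation = 0) {
  stopifnot(inherits(protocol, "stimulus_protocol"),
            inherits(model, "release_model"))
  dt <- protocol$cycle_duration
  starts <- cycle_starts(protocol)
  rates <- release_rate(model, protocol$contrasts)
  res <- withr_seed(seed, {
    times <- numeric(0); quanta <- integer(0)
    for (i in seq_len(protocol$n_cycles)) {
      n <- stats::rpois(1L, rates[i] * dt)
      if (n == 0L) next
      ph <- if (phase_lock) {
        p <- stats::rnorm(n, phase_mean, phase_sd)
        p - floor(p)                      # wrap into [0, 1)
      } else stats::runif(n)
      times <- c(times, starts[i] + sort(ph) * dt)
      quanta <- c(quanta, sample.int(length(model$mvr_weights), n,
                                     replace = TRUE,
                                     prob = model$mvr_weights))
    }
    list(times = times, quanta = quanta)
  })
  ord <- order(res$times)
  times <- res$times[ord]; quanta <- res$quanta[ord]
  # drop coincident or too-close events (strict monotonicity + optional gap)
  if (length(times) > 1L) {
    keep <- rep(TRUE, length(times)); last <- times[1L]
    for (j in 2L:length(times)) {
      if (times[j] - last <= max(min_separation, 1e-9)) keep[j] <- FALSE
      else last <- times[j]
    }
    times <- times[keep]; quanta <- quanta[keep]
  }
  quantal_series(times, quanta, quantal_amplitude = model$quantal_amplitude)
}

#' Imaging model for linescan rendering
#'
#' Geometry, optics and noise of the simulated linescan: pixel grid, Gaussian
#' point sources standing for active zones, acquisition rate, additive noise
#' and slow linear bleaching.
#'
#' @param n_positions number of pixels along the scanned line.
#' @param pixel_size pixel size in micrometres.
#' @param line_rate lines per second in Hz (default 1000, i.e. 1 kHz).
#' @param source_centers active-zone centres in micrometres along the line.
#' @param source_widths Gaussian sigma of each source, micrometres.
#' @param noise_sd additive Gaussian noise, in dF/F0 units (scaled by the
#'   local baseline when rendering).
#' @param shot_noise if `TRUE`, noise variance additionally scales with the
#'   instantaneous signal (shot-like noise).
#' @param bleach_slope fractional fluorescence loss per second (linear bleach).
#' @param baseline_F0 baseline fluorescence at a source centre, arbitrary units.
#' @return an `imaging_model` object.
#' @export
imaging_model <- function(n_positions = 32L, pixel_size = 0.25,
                          line_rate = 1000, source_centers = 4,
                          source_widths = 0.4, noise_sd = 0.05,
                          shot_noise = FALSE,
                          bleach_slope = 0, baseline_F0 = 100) {
  stopifnot(line_rate > 0, all(source_widths > 0), noise_sd >= 0,
            n_positions >= 4L, baseline_F0 > 0,
            length(source_centers) == length(source_widths) ||
              length(source_widths) == 1L)
  if (length(source_widths) == 1L)
    source_widths <- rep(source_widths, length(source_centers))
  structure(list(n_positions = as.integer(n_positions),
                 pixel_size = pixel_size, line_rate = line_rate,
                 source_centers = source_centers,
                 source_widths = source_widths,
                 noise_sd = noise_sd, shot_noise = shot_noise,
                 bleach_slope = bleach_slope, baseline_F0 = baseline_F0),
            class = "imaging_model")
}

#' Render a linescan recording from ground-truth release
#'
#' Forward model inverted by the decomposition pipeline. Each source k has a
#' unit-peak spatial profile `G_k(x) = exp(-(x - c_k)^2 / (2 sigma_k^2))`; the
#' fluorescence at pixel x and time t is
#' \deqn{F(x,t) = \sum_k G_k(x)\, F_0 (1 - b t)\, (1 + \Delta F/F_0_k(t)) + \epsilon,}
#' where the dF/F0 trace of source k is the sum over its events of
#' `quanta * quantal_amplitude * h(t - t_event)` with `h` the peak-normalized
#' reporter kernel, `b` the bleach slope, and `epsilon` Gaussian noise with SD
#' `noise_sd * F0` (optionally signal-scaled). With a single source all events
#' belong to it; with several, events are split round-robin unless `source_of`
#' assigns them explicitly.
#'
#' @param truth a [quantal_series()] of ground-truth events.
#' @param kernel a [glu_kernel()].
#' @param imaging an [imaging_model()].
#' @param seed integer seed for the noise.
#' @param quantal_amplitude dF/F0 per vesicle; defaults to the value attached
#'   to `truth`.
#' @param amplitude_cv fractional spread of a single quantum: an event of k
#'   quanta is rendered with amplitude drawn from
#'   `Normal(k q, (amplitude_cv * q)^2)`, truncated at a tenth of a quantum
#'   (the spread of the multivesicular packet is that of the unitary signal).
#' @param source_of optional integer vector assigning each event to a source.
#' @return a `linescan_recording`: list with `values` (positions x time
#'   matrix, arbitrary fluorescence units), `line_rate`, `pixel_size`,
#'   `duration`, `positions` (um) and the ground truth in attribute `truth`.
#' @export
render_linescan <- function(truth, kernel, imaging, seed = 1L,
                            quantal_amplitude = truth$quantal_amplitude,
                            amplitude_cv = 0, source_of = NULL) {
  stopifnot(inherits(truth, "quantal_series"),
            inherits(kernel, "glu_kernel"),
            inherits(imaging, "imaging_model"))
  if (is.na(quantal_amplitude))
    stop("quantal_amplitude is required (none attached to truth)")
  n_src <- length(imaging$source_centers)
  duration <- attr(truth, "duration")
  if (is.null(duration))
    duration <- if (length(truth$times)) max(truth$times) + 10 * kernel$tau_f else 1
  if (length(truth$times) && max(truth$times) > duration)
    stop("event times extend beyond the recording duration")
  nt <- as.integer(round(duration * imaging$line_rate))
  tgrid <- (seq_len(nt) - 1L) / imaging$line_rate
  x <- (seq_len(imaging$n_positions) - 1L) * imaging$pixel_size

  if (is.null(source_of)) {
    source_of <- if (n_src == 1L) rep(1L, length(truth$times))
    else rep_len(seq_len(n_src), length(truth$times))
  }
  stopifnot(length(source_of) == length(truth$times))

  # per-event rendered amplitudes, with optional single-quantum jitter
  amps <- truth$quanta * quantal_amplitude
  if (amplitude_cv > 0 && length(amps)) {
    amps <- withr_seed(seed + 7L, {
      jitter <- stats::rnorm(length(amps), 0,
                             amplitude_cv * quantal_amplitude)
      pmax(amps + jitter, 0.1 * quantal_amplitude)
    })
  }

  # per-source dF/F0 trace: superposed peak-normalized kernels
  dff <- matrix(0, nrow = n_src, ncol = nt)
  for (i in seq_along(truth$times)) {
    s <- source_of[i]
    i0 <- as.integer(floor(truth$times[i] * imaging$line_rate)) + 1L
    if (i0 > nt) next
    idx <- i0:nt
    dff[s, idx] <- dff[s, idx] +
      amps[i] * kernel_eval(kernel, tgrid[idx] - truth$times[i],
                            normalize = TRUE)
  }

  bleach <- 1 - imaging$bleach_slope * tgrid
  F0 <- imaging$baseline_F0
  values <- matrix(0, nrow = imaging$n_positions, ncol = nt)
  for (s in seq_len(n_src)) {
    G <- exp(-(x - imaging$source_centers[s])^2 /
               (2 * imaging$source_widths[s]^2))
    values <- values + outer(G, F0 * bleach * (1 + dff[s, ]))
  }
  if (imaging$noise_sd > 0) {
    noise <- withr_seed(seed, {
      e <- matrix(stats::rnorm(length(values)), nrow = nrow(values))
      if (imaging$shot_noise)
        e * imaging$noise_sd * sqrt(pmax(values, 0) * F0)
      else e * imaging$noise_sd * F0
    })
    values <- values + noise
  }
  structure(list(values = values, line_rate = imaging$line_rate,
                 pixel_size = imaging$pixel_size, duration = nt / imaging$line_rate,
                 positions = x),
            class = "linescan_recording",
            truth = truth, imaging = imaging, kernel = kernel,
            source_of = source_of)
}

#' @export
print.linescan_recording <- function(x, ...) {
  cat(sprintf("Linescan recording: %d positions x %d lines at %g Hz (%.3g s)\n",
              nrow(x$values), ncol(x$values), x$line_rate, x$duration))
  invisible(x)
}

#' Simulate a full synthetic recording in one call
#'
#' Convenience wrapper: [simulate_release()] then [render_linescan()], with
#' the recording duration pinned to the protocol duration.
#'
#' @inheritParams simulate_release
#' @inheritParams render_linescan
#' @param kernel a [glu_kernel()].
#' @param imaging an [imaging_model()].
#' @return a `linescan_recording` with ground truth attached.
#' @export
simulate_recording <- function(protocol, model, kernel = glu_kernel(),
                               imaging = imaging_model(), seed = 1L,
                               phase_lock = FALSE, min_separation = 0) {
  truth <- simulate_release(protocol, model, seed = seed,
                            phase_lock = phase_lock,
                            min_separation = min_separation)
  attr(truth, "duration") <- protocol$duration
  render_linescan(truth, kernel, imaging, seed = seed + 1L,
                  amplitude_cv = model$amplitude_cv)
}
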
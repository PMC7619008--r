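#' Bleach-correct a fluorescence trace and convert to dF/F0
#'
#' Slow photobleaching is removed as a linear function of time, fitted
#' robustly so that release transients do not bias the slope (an ordinary
#' least-squares line is fitted, then refitted on samples within 2.5 robust
#' SDs of it). The baseline F0 is taken as the most frequent value (the mode)
#' of the corrected trace, estimated as the maximum of a Gaussian kernel
#' density with Silverman's bandwidth; a histogram mode is available as a
#' fallback. The returned trace is (F - F0) / F0.
#'
#' @param trace a `fluorescence_trace` (field `f`, a.u.; `line_rate`, Hz) or a
#'   plain numeric vector with `line_rate` supplied.
#' @param line_rate sampling rate in Hz, required if `trace` is a bare vector.
#' @param mode_estimator `"kde"` (default) or `"histogram"`.
#' @return the trace with added fields `dff` (dF/F0), `f0` (a.u.) and
#'   `bleach_params` (intercept, slope in a.u. per second).
#' @export
correct_baseline <- function(trace, line_rate = NULL,
                             mode_estimator = c("kde", "histogram")) {
  mode_estimator <- match.arg(mode_estimator)
  if (is.numeric(trace)) {
    if (is.null(line_rate)) stop("line_rate is required for a bare vector")
    trace <- structure(list(f = trace, line_rate = line_rate),
                       class = "fluorescence_trace")
  }
  f <- trace$f
  rate <- trace$line_rate
  if (length(f) < rate) stop("trace shorter than 1 s of samples")
  t <- (seq_along(f) - 1L) / rate

  # robust line (redescending bisquare M-estimator): release transients are
  # large one-sided excursions that an ordinary least-squares line would tilt
  # toward, while the bisquare weight zeroes them out of the bleach trend
  fit <- if (stats::sd(f) > 0)
    MASS::rlm(f ~ t, psi = MASS::psi.bisquare, maxit = 50)
  else stats::lm(f ~ t)
  slope <- stats::coef(fit)[2L]
  corrected <- f - slope * t

  f0 <- if (diff(range(corrected)) < 1e-9 * max(1, abs(corrected[1L]))) {
    corrected[1L]
  } else if (mode_estimator == "kde") {
    d <- stats::density(corrected, bw = "nrd0")
    d$x[which.max(d$y)]
  } else {
    h <- graphics::hist(corrected, breaks = "FD", plot = FALSE)
    h$mids[which.max(h$counts)]
  }
  if (f0 <= 0)
    stop("estimated baseline F0 <= 0; trace is not interpretable as fluorescence")
  trace$dff <- (corrected - f0) / f0
  trace$f0 <- f0
  trace$bleach_params <- c(intercept = unname(fit$coefficients[1L]),
                           slope = unname(slope))
  trace
}

#' Wiener deconvolution of a dF/F0 trace against the reporter kernel
#'
#' Estimates the underlying impulse train of release events by frequency-
#' domain Wiener filtering:
#' \deqn{\hat d(\omega) = \frac{H^*(\omega)}{|H(\omega)|^2 + N/S}\, \hat f(\omega),}
#' where H is the transform of the peak-normalized kernel, and N/S is the
#' noise-to-signal power ratio. With `noise_power = "auto"` the noise floor is
#' estimated from the high-frequency tail (above 250 Hz) of the trace power
#' spectrum and the signal power from the remainder. The output is a time
#' series in which each release event appears approximately as an impulse
#' whose height matches the event's peak dF/F0.
#'
#' @param trace a baseline-corrected trace (needs field `dff`) or a numeric
#'   dF/F0 vector with `line_rate`.
#' @param kernel a [glu_kernel()].
#' @param noise_power `"auto"` or a positive number: the N/S power ratio used
#'   in the filter (a.u. squared, relative to unit signal power).
#' @param line_rate sampling rate in Hz when `trace` is a bare vector.
#' @param tail_hz frequency above which the spectrum is treated as pure noise
#'   for the automatic estimate (default 250 Hz).
#' @return a `deconvolved_trace`: list with `d` (impulse-domain series),
#'   `line_rate`, `nsr` (noise-to-signal ratio used).
#' @export
wiener_deconvolve <- function(trace, kernel, noise_power = "auto",
                              line_rate = NULL, tail_hz = 250) {
  if (is.numeric(trace)) {
    if (is.null(line_rate)) stop("line_rate is required for a bare vector")
    trace <- list(dff = trace, line_rate = line_rate)
  }
  if (is.null(trace$dff))
    stop("trace has no dF/F0 field; run correct_baseline() first")
  y <- trace$dff
  rate <- trace$line_rate
  n <- length(y)

  h <- kernel_sample(kernel, rate, normalize = TRUE)
  if (length(h) > n) h <- h[seq_len(n)]
  npad <- stats::nextn(n + length(h), 2)
  H <- stats::fft(c(h, rep(0, npad - length(h))))
  Y <- stats::fft(c(y, rep(0, npad - n)))

  if (identical(noise_power, "auto")) {
    freqs <- (seq_len(npad) - 1L) / npad * rate
    freqs <- pmin(freqs, rate - freqs)       # two-sided -> folded
    pw <- Mod(Y)^2 / npad
    tail_hz <- min(tail_hz, 0.45 * rate)
    noise_bins <- freqs >= tail_hz
    if (!any(noise_bins)) noise_bins <- freqs >= stats::median(freqs)
    npow <- stats::median(pw[noise_bins])
    spow <- max(mean(pw[!noise_bins]) - npow, npow * 1e-3, 1e-300)
    nsr <- npow / spow
  } else {
    if (!is.numeric(noise_power) || noise_power <= 0)
      stop("noise_power must be \"auto\" or a positive number")
    nsr <- noise_power
  }

  D <- Conj(H) * Y / (Mod(H)^2 + nsr)
  d <- Re(stats::fft(D, inverse = TRUE)) / npad
  structure(list(d = d[seq_len(n)], line_rate = rate, nsr = nsr),
            class = "deconvolved_trace")
}

#' Detect release events in a deconvolved trace
#'
#' Events are local maxima of the deconvolved series exceeding a threshold of
#' `threshold_sd` baseline standard deviations, where the baseline SD is
#' estimated robustly (median absolute deviation scaled by 1.4826) so that the
#' events themselves do not inflate it. Each event is timed at its local
#' maximum. A plateau of tied maxima yields a single event at its first
#' sample; maxima closer than the refractory window to a larger accepted
#' event are suppressed.
#'
#' The amplitude readout is, by default, the sum of the deconvolved series
#' over a short window around the maximum (`amplitude = "integral"`): for an
#' ideal linear deconvolution this equals the event's peak dF/F0 regardless
#' of where the event falls between samples, whereas the raw sample maximum
#' (`amplitude = "peak"`) fluctuates by tens of percent with the sub-sample
#' event phase, which blurs the quantal amplitude clusters.
#'
#' @param deconvolved a [wiener_deconvolve()] result, or a numeric vector with
#'   `line_rate`.
#' @param threshold_sd detection threshold in SD multiples (default 3.5, the
#'   middle of the usual 3-4 SD working range).
#' @param refractory minimum separation between events in seconds
#'   (default 0.005).
#' @param amplitude `"integral"` (default) or `"peak"`; see Details.
#' @param integration_window half-width in seconds of the summation window
#'   for the integral readout (default 0.003).
#' @param line_rate sampling rate in Hz when a bare vector is given.
#' @return an `event_train`: list with `times` (s, strictly increasing),
#'   `amplitudes` (deconvolved units), `threshold_used`, `noise_sd`.
#' @export
detect_events <- function(deconvolved, threshold_sd = 3.5,
                          refractory = 0.005,
                          amplitude = c("integral", "peak"),
                          integration_window = 0.003, line_rate = NULL) {
  amplitude <- match.arg(amplitude)
  if (is.numeric(deconvolved)) {
    if (is.null(line_rate)) stop("line_rate is required for a bare vector")
    deconvolved <- list(d = deconvolved, line_rate = line_rate)
  }
  stopifnot(threshold_sd > 0)
  d <- deconvolved$d
  rate <- deconvolved$line_rate
  n <- length(d)
  sd0 <- stats::mad(d, center = stats::median(d))
  # numerically noiseless traces: floor the noise scale so deconvolution
  # rounding artifacts (~1e-12 of the signal) never count as events
  sd0 <- max(sd0, 1e-9 * max(abs(d)))
  thr <- stats::median(d) + threshold_sd * sd0

  if (n < 3L || sd0 == 0 && all(d == d[1L])) {
    return(structure(list(times = numeric(0), amplitudes = numeric(0),
                          threshold_used = threshold_sd, noise_sd = sd0),
                     class = "event_train"))
  }
  # local maxima; plateaus credited to their first sample
  left <- c(-Inf, d[-n])
  right <- c(d[-1L], -Inf)
  cand <- which(d > left & d >= right & d > thr)
  if (!length(cand)) {
    return(structure(list(times = numeric(0), amplitudes = numeric(0),
                          threshold_used = threshold_sd, noise_sd = sd0),
                     class = "event_train"))
  }
  # greedy refractory suppression, largest amplitude first: monotone in the
  # threshold (raising it can only remove events)
  ord <- cand[order(d[cand], decreasing = TRUE)]
  min_gap <- refractory * rate
  accepted <- integer(0)
  for (i in ord) {
    if (!length(accepted) || all(abs(accepted - i) >= min_gap))
      accepted <- c(accepted, i)
  }
  accepted <- sort(accepted)
  amps <- if (amplitude == "peak") d[accepted]
  else {
    w <- max(1L, as.integer(round(integration_window * rate)))
    vapply(accepted, function(i)
      sum(d[max(1L, i - w):min(n, i + w)]), numeric(1))
  }
  # noise artifacts integrate to ~0 (the filter's side lobes cancel) while
  # real impulses carry their full mass, so in integral mode candidates whose
  # summed amplitude stays within the noise scale are discarded; nonpositive
  # amplitudes cannot be release events in either mode
  keep <- if (amplitude == "integral") amps > threshold_sd * sd0
  else amps > 0
  accepted <- accepted[keep]; amps <- amps[keep]
  structure(list(times = (accepted - 1L) / rate,
                 amplitudes = amps,
                 threshold_used = threshold_sd,
                 noise_sd = sd0),
            class = "event_train")
}

#' @export
print.event_train <- function(x, ...) {
  cat(sprintf("Event train: %d events (threshold %.2g SD, noise SD %.3g)\n",
              length(x$times), x$threshold_used, x$noise_sd))
  invisible(x)
}
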
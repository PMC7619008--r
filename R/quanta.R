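#' Partition event amplitudes into integer numbers of quanta
#'
#' Glutamate transients of varying amplitude are integer multiples of a
#' unitary event (one vesicle). The unit amplitude q is estimated by maximum
#' likelihood under a Gaussian mixture whose components sit at integer
#' multiples k*q (k = 1..K) with spread `sigma_k = cv * q * sqrt(k)` (variance
#' additivity of synchronously fused quanta; a fixed-sigma alternative is
#' available). Each event is then assigned the k with the highest component
#' likelihood.
#'
#' @param train an `event_train` from [detect_events()] (fields `times`,
#'   `amplitudes`), or a numeric amplitude vector.
#' @param quantal_amplitude optional known unit amplitude; required when fewer
#'   than 10 events are available, otherwise used as-is (no estimation).
#' @param cv assumed fractional spread of a single quantum (default 0.15).
#' @param max_quanta largest vesicle count considered per event (default 10).
#' @param spread `"sqrt_k"` (default, SD grows as sqrt(k)) or `"fixed"`.
#' @param polarity passed through to the result.
#' @return a [quantal_series()] with the estimated `quantal_amplitude`
#'   attached, plus attribute `loglik`.
#' @export
cluster_quanta <- function(train, quantal_amplitude = NULL, cv = 0.15,
                           max_quanta = 10L, spread = c("sqrt_k", "fixed"),
                           polarity = "unknown") {
  spread <- match.arg(spread)
  if (is.numeric(train))
    train <- list(times = seq_along(train), amplitudes = train)
  a <- train$amplitudes
  if (!length(a))
    return(quantal_series(numeric(0), integer(0),
                          quantal_amplitude = quantal_amplitude %||% NA_real_,
                          polarity = polarity))
  if (any(a <= 0)) stop("event amplitudes must be positive")

  if (is.null(quantal_amplitude)) {
    if (length(a) < 10L)
      stop("fewer than 10 events: supply quantal_amplitude explicitly")
    qhat <- estimate_quantum(a, cv = cv, max_quanta = max_quanta,
                             spread = spread)
  } else {
    stopifnot(quantal_amplitude > 0)
    qhat <- quantal_amplitude
  }
  k <- assign_quanta(a, qhat, max_quanta)
  quantal_series(train$times, k, quantal_amplitude = qhat,
                 polarity = polarity)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# The unit amplitude is anchored to the first (lowest-amplitude) mode of the
# amplitude density — univesicular events are the most common class and define
# it — and refined by profile maximum likelihood in a window around that
# anchor. The anchoring sidesteps the period-halving degeneracy of a free ML
# search (q/2 with doubled indices always scores at least as well when the
# component spread scales with q).
estimate_quantum <- function(a, cv, max_quanta, spread) {
  if (stats::sd(a) == 0) {
    q0 <- a[1L]
  } else {
    d <- stats::density(a, bw = "nrd0")
    peak <- c(FALSE, diff(sign(diff(d$y))) < 0, FALSE)
    modes <- d$x[peak & d$y > 0.05 * max(d$y)]
    q0 <- if (length(modes)) min(modes) else d$x[which.max(d$y)]
  }
  lo <- 0.65 * q0; hi <- 1.45 * q0
  qs <- seq(lo, hi, length.out = 200L)
  ll <- vapply(qs, function(q) quantal_loglik(a, q, cv, max_quanta, spread),
               numeric(1))
  # flat-likelihood guard: no quantal structure to latch onto
  if (max(ll) - min(ll) < 1e-6 * max(1, abs(max(ll))))
    stop("quantal likelihood surface is flat; supply quantal_amplitude manually")
  qhat <- qs[which.max(ll)]
  # polish by soft EM: responsibilities over the integer components, then the
  # weighted least-squares update for q (for spread ~ sqrt(k) that is
  # q = sum_i sum_k r_ik a_i / sum_i sum_k r_ik k). Solving for q by least
  # squares rather than joint ML removes the O(cv^2) downward bias that the
  # q-tied component spread puts on the profile likelihood, and the soft
  # assignment keeps boundary-straddling events from dragging q with them.
  kk <- seq_len(max_quanta)
  w <- rep(1 / max_quanta, max_quanta)
  for (it in 1:50) {
    sdk <- if (spread == "sqrt_k") cv * qhat * sqrt(kk) else rep(cv * qhat, max_quanta)
    dens <- vapply(seq_along(kk), function(j)
      w[j] * stats::dnorm(a, kk[j] * qhat, pmax(sdk[j], 1e-12)),
      numeric(length(a)))
    dens <- matrix(dens, nrow = length(a))
    r <- dens / pmax(rowSums(dens), 1e-300)
    w <- pmax(colSums(r), 1e-12); w <- w / sum(w)
    qnew <- if (spread == "sqrt_k") {
      # minimizes sum_ik r_ik (a_i - k q)^2 / k
      sum(r * a) / sum(sweep(r, 2, kk, "*"))
    } else {
      sum(sweep(r, 2, kk, "*") * a) / sum(sweep(r, 2, kk^2, "*"))
    }
    if (abs(qnew - qhat) < 1e-12 * qhat) { qhat <- qnew; break }
    qhat <- qnew
  }
  qhat
}

quantal_loglik <- function(a, q, cv, max_quanta, spread) {
  k <- seq_len(max_quanta)
  sdk <- if (spread == "sqrt_k") cv * q * sqrt(k) else rep(cv * q, max_quanta)
  sdk <- pmax(sdk, 1e-12)
  dens <- vapply(seq_along(k), function(j)
    stats::dnorm(a, mean = k[j] * q, sd = sdk[j]), numeric(length(a)))
  dens <- matrix(dens, nrow = length(a))
  # responsibility-weighted component weights (single EM step from uniform)
  w <- colSums(dens / pmax(rowSums(dens), 1e-300))
  w <- w / sum(w)
  sum(log(pmax(dens %*% w, 1e-300)))
}

assign_quanta <- function(a, q, max_quanta) {
  pmin(pmax(as.integer(round(a / q)), 1L), as.integer(max_quanta))
}

#' Classify the ON/OFF polarity of a synapse from step responses
#'
#' Recordings begin with 1-s steps of positive and negative contrast; an ON
#' synapse releases during the positive step, an OFF synapse during the
#' negative one. The classification compares event rates in the two annotated
#' windows and returns `"unknown"` when neither rate exceeds the other by the
#' margin.
#'
#' @param series a [quantal_series()].
#' @param positive_window,negative_window two-element `c(start, end)` times in
#'   seconds delimiting the positive- and negative-contrast steps.
#' @param margin multiplicative margin: polarity is called only if one rate
#'   exceeds `margin` times the other (default 1.5).
#' @return `"ON"`, `"OFF"` or `"unknown"`.
#' @export
classify_polarity <- function(series, positive_window, negative_window,
                              margin = 1.5) {
  stopifnot(inherits(series, "quantal_series"),
            length(positive_window) == 2L, length(negative_window) == 2L,
            margin >= 1)
  rate_in <- function(w) {
    n <- sum(series$times >= w[1L] & series$times < w[2L])
    n / (w[2L] - w[1L])
  }
  rp <- rate_in(positive_window)
  rn <- rate_in(negative_window)
  if (rp > margin * rn && rp > 0) "ON"
  else if (rn > margin * rp && rn > 0) "OFF"
  else "unknown"
}

#' Run the full quantal decomposition on a linescan recording
#'
#' Convenience chain over the six analysis steps: spatial decomposition,
#' time-series extraction, baseline correction, Wiener deconvolution, event
#' detection and quantal clustering. Components flagged by the spatial width
#' criterion are skipped.
#'
#' @param recording a `linescan_recording`.
#' @param kernel a [glu_kernel()].
#' @param threshold_sd,refractory passed to [detect_events()].
#' @param noise_power passed to [wiener_deconvolve()].
#' @param quantal_amplitude,cv passed to [cluster_quanta()].
#' @param max_components passed to [fit_spatial_profile()].
#' @return a list of [quantal_series()], one per retained spatial component,
#'   with the intermediate stages attached as attributes (`profile`, `trace`,
#'   `deconvolved`, `train`).
#' @export
decompose_recording <- function(recording, kernel = glu_kernel(),
                                threshold_sd = 3.5, refractory = 0.005,
                                noise_power = "auto",
                                quantal_amplitude = NULL, cv = 0.15,
                                max_components = 3L) {
  profile <- fit_spatial_profile(recording, max_components = max_components)
  traces <- extract_timeseries(recording, profile)
  out <- list()
  for (tr in traces) {
    if (isTRUE(tr$excluded)) next
    tr <- correct_baseline(tr)
    dec <- wiener_deconvolve(tr, kernel, noise_power = noise_power)
    train <- detect_events(dec, threshold_sd = threshold_sd,
                           refractory = refractory)
    qs <- if (length(train$times) == 0L)
      quantal_series(numeric(0), integer(0))
    else if (length(train$times) < 10L && is.null(quantal_amplitude))
      cluster_quanta(train, quantal_amplitude = stats::median(train$amplitudes),
                     cv = cv)
    else cluster_quanta(train, quantal_amplitude = quantal_amplitude, cv = cv)
    attr(qs, "profile") <- profile
    attr(qs, "trace") <- tr
    attr(qs, "deconvolved") <- dec
    attr(qs, "train") <- train
    out[[length(out) + 1L]] <- qs
  }
  out
}
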
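#' Count vesicles and events per stimulus cycle
#'
#' Assigns each release event to a stimulus cycle (half-open intervals
#' `[cycle_start, cycle_end)`) and tallies, per cycle, the event count, the
#' total vesicle count (sum of quanta) and the mean event amplitude in quanta
#' (NA for empty cycles).
#'
#' @param series a [quantal_series()]; shares its time origin with `protocol`.
#' @param protocol a [make_stimulus()] protocol.
#' @return a `cyclewise_counts` object: data frame with columns `cycle`,
#'   `contrast`, `events`, `vesicles`, `mean_amplitude`, and attribute
#'   `frequency`.
#' @examples
#' p <- make_stimulus(60, repeats = 1, randomize = FALSE)
#' s <- quantal_series(c(0.03, 0.12), c(1L, 2L))
#' count_per_cycle(s, p)   # 2 events, 3 vesicles, mean amplitude 1.5
#' @export
count_per_cycle <- function(series, protocol) {
  stopifnot(inherits(series, "quantal_series"),
            inherits(protocol, "stimulus_protocol"))
  orphans <- series$times[series$times < 0 |
                            series$times >= protocol$duration]
  if (length(orphans))
    stop("events outside the protocol at t = ",
         paste(signif(orphans, 6), collapse = ", "))
  idx <- findInterval(series$times, cycle_starts(protocol))
  df <- data.frame(cycle = seq_len(protocol$n_cycles),
                   contrast = protocol$contrasts,
                   events = 0L, vesicles = 0L,
                   mean_amplitude = NA_real_)
  if (length(idx)) {
    ev <- tabulate(idx, nbins = protocol$n_cycles)
    vs <- vapply(seq_len(protocol$n_cycles),
                 function(i) sum(series$quanta[idx == i]), numeric(1))
    df$events <- ev
    df$vesicles <- as.integer(vs)
    df$mean_amplitude <- ifelse(ev > 0, vs / ev, NA_real_)
  }
  structure(df, class = c("cyclewise_counts", "data.frame"),
            frequency = protocol$frequency)
}

#' Mean release rate per contrast
#'
#' Vesicle release rate in vesicles per second: mean vesicles per cycle times
#' the stimulus frequency.
#'
#' @param counts a [count_per_cycle()] result.
#' @return data frame with `contrast`, `mean_vesicles` (per cycle),
#'   `rate` (vesicles/s), `n_cycles`.
#' @export
release_rate_per_contrast <- function(counts) {
  stopifnot(inherits(counts, "cyclewise_counts"))
  freq <- attr(counts, "frequency")
  agg <- stats::aggregate(vesicles ~ contrast, data = counts, FUN = mean)
  n <- stats::aggregate(vesicles ~ contrast, data = counts, FUN = length)
  data.frame(contrast = agg$contrast,
             mean_vesicles = agg$vesicles,
             rate = agg$vesicles * freq,
             n_cycles = n$vesicles)
}

#' Fit a Hill contrast-response function
#'
#' Mean vesicles per cycle versus contrast is fitted with
#' \deqn{r(c) = r_{max} \frac{c^n}{c^n + C_{1/2}^n}}
#' by bounded Levenberg-Marquardt least squares. Because the responses are
#' trial-averaged counts, the fit is weighted by the reciprocal mean
#' (Poisson-like variance); starting values are tried over a small grid of
#' `(c_half, hill_n)` and the best weighted fit kept, which stops occasional
#' runs into the parameter bounds on noisy data. `C_1/2` is the half-maximal
#' contrast; its confidence interval comes from the fit covariance. The Hill
#' exponent is bounded to \[0.5, 8\] and `C_1/2` to (1, 100\]% to keep fits on
#' shallow data away from degenerate corners. Monotone-decreasing data are
#' flagged (the Hill form is monotone increasing).
#'
#' @param counts a [count_per_cycle()] result, or a data frame with columns
#'   `contrast` and `mean_vesicles`.
#' @return a `contrast_response_fit`: list with `r_max`, `c_half`, `hill_n`,
#'   `vcov`, `c_half_ci` (95%), `flagged`, `flag_reason`, `data`, `fit`.
#' @export
fit_hill <- function(counts) {
  df <- if (inherits(counts, "cyclewise_counts"))
    release_rate_per_contrast(counts)
  else as.data.frame(counts)
  stopifnot(all(c("contrast", "mean_vesicles") %in% names(df)))
  df <- df[order(df$contrast), ]
  if (length(unique(df$contrast)) < 4L)
    stop("Hill fit needs >= 4 distinct contrasts")

  flagged <- FALSE; flag_reason <- character(0)
  if (stats::cor(df$contrast, df$mean_vesicles, method = "spearman") < 0) {
    flagged <- TRUE
    flag_reason <- c(flag_reason,
                     "response decreases with contrast; Hill form is increasing")
  }
  rmax0 <- max(df$mean_vesicles)
  if (rmax0 <= 0) stop("all responses are zero; nothing to fit")
  chalf0 <- stats::approx(df$mean_vesicles / rmax0, df$contrast, xout = 0.5,
                          ties = mean, rule = 2)$y
  if (is.na(chalf0)) chalf0 <- stats::median(df$contrast)
  chalf0 <- min(max(chalf0, 2), 99)
  w <- 1 / pmax(df$mean_vesicles, 0.05)
  starts <- expand.grid(ch = unique(c(chalf0, 20, 40, 60)), n = c(1, 2, 4))
  fit <- NULL; best_rss <- Inf
  for (i in seq_len(nrow(starts))) {
    f <- tryCatch(minpack.lm::nlsLM(
      mean_vesicles ~ r_max * contrast^hill_n /
        (contrast^hill_n + c_half^hill_n),
      data = df, weights = w,
      start = list(r_max = rmax0, c_half = starts$ch[i],
                   hill_n = starts$n[i]),
      lower = c(r_max = 0, c_half = 1 + 1e-6, hill_n = 0.5),
      upper = c(r_max = Inf, c_half = 100, hill_n = 8),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(f)) next
    rss <- sum(w * stats::residuals(f, type = "response")^2)
    if (rss < best_rss) { best_rss <- rss; fit <- f }
  }
  if (is.null(fit))
    stop("Hill fit failed to converge from any starting point")
  cf <- stats::coef(fit)
  V <- tryCatch(stats::vcov(fit), error = function(e) matrix(NA_real_, 3, 3))
  at_bound <- cf[["c_half"]] >= 100 - 1e-6 || cf[["c_half"]] <= 1 + 1e-5
  if (at_bound) {
    flagged <- TRUE
    flag_reason <- c(flag_reason, "c_half at parameter bound")
  }
  se <- suppressWarnings(sqrt(V["c_half", "c_half"]))
  structure(list(r_max = cf[["r_max"]], c_half = cf[["c_half"]],
                 hill_n = cf[["hill_n"]], vcov = V,
                 c_half_ci = cf[["c_half"]] + c(-1, 1) * 1.96 * se,
                 flagged = flagged, flag_reason = flag_reason,
                 data = df, fit = fit),
            class = "contrast_response_fit")
}

#' @export
print.contrast_response_fit <- function(x, ...) {
  cat(sprintf(
    "Hill contrast-response fit: r_max = %.3g vesicles/cycle, C1/2 = %.3g%% (95%% CI %.3g-%.3g), n = %.3g%s\n",
    x$r_max, x$c_half, x$c_half_ci[1L], x$c_half_ci[2L], x$hill_n,
    if (x$flagged) paste0(" [FLAGGED: ", paste(x$flag_reason, collapse = "; "), "]")
    else ""))
  invisible(x)
}

#' Maximum contrast gain around the half-maximal contrast
#'
#' Contrast gain is the change in vesicle release rate per unit change in
#' contrast; it is maximal near `C_1/2` and is measured over the window
#' `C_1/2` plus/minus 10% contrast. Release rates within the window are
#' normalized to the rate at the window's lowest contrast, and the relative
#' gain is the ordinary-least-squares slope of relative rate versus contrast.
#'
#' @param counts a [count_per_cycle()] result.
#' @param c_half half-maximal contrast in percent (e.g. from [fit_hill()]).
#' @param half_width half-width of the gain window in percent contrast
#'   (default 10, giving the standard 20%-wide window).
#' @return a `gain_result`: list with `slope` (relative rate per % contrast),
#'   `intercept`, `window`, `normalization_contrast`, `data`.
#' @export
contrast_gain <- function(counts, c_half, half_width = 10) {
  rr <- release_rate_per_contrast(counts)
  window <- c(c_half - half_width, c_half + half_width)
  inw <- rr$contrast >= window[1L] & rr$contrast <= window[2L]
  if (sum(inw) < 3L)
    stop(sprintf("need >= 3 contrasts inside the gain window [%g, %g]%%",
                 window[1L], window[2L]))
  d <- rr[inw, ]
  ref_contrast <- min(d$contrast)
  ref <- d$rate[d$contrast == ref_contrast][1L]
  if (ref <= 0) {
    # fall back to the smallest positive rate so relative rates stay finite
    pos <- d$rate[d$rate > 0]
    if (!length(pos)) stop("all rates in the gain window are zero")
    ref <- min(pos)
  }
  d$relative_rate <- d$rate / ref
  fit <- stats::lm(relative_rate ~ contrast, data = d)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 window = window,
                 normalization_contrast = ref_contrast,
                 data = d, fit = fit),
            class = "gain_result")
}

#' @export
print.gain_result <- function(x, ...) {
  cat(sprintf(
    "Contrast gain: slope %.4g (relative rate per %% contrast) over [%g, %g]%%, normalized at %g%%\n",
    x$slope, x$window[1L], x$window[2L], x$normalization_contrast))
  invisible(x)
}

#' Factorize the vesicle code into event rate and event amplitude
#'
#' The vesicle release rate at each contrast is decomposed, identically, into
#' the product of the event rate and the mean event amplitude (quanta per
#' event): changes of gain carried by firing more events are thereby separated
#' from changes carried by packing more vesicles into each event
#' (multivesicular release). Cycles with no events contribute zero rate and
#' are excluded from the amplitude mean; a contrast whose cycles are all empty
#' has undefined amplitude (NA).
#'
#' @param counts a [count_per_cycle()] result.
#' @param normalize_to `"lowest"` (default) normalizes the relative columns to
#'   the lowest contrast with a defined amplitude; `"none"` skips them.
#' @return data frame with, per contrast: `event_rate` (events/s),
#'   `mean_amplitude` (quanta/event), `vesicle_rate` (vesicles/s, identically
#'   `event_rate * mean_amplitude`), and relative versions.
#' @export
factorize_code <- function(counts, normalize_to = c("lowest", "none")) {
  normalize_to <- match.arg(normalize_to)
  stopifnot(inherits(counts, "cyclewise_counts"))
  if (length(unique(counts$contrast)) < 2L)
    stop("factorization needs >= 2 contrasts")
  freq <- attr(counts, "frequency")
  sp <- split(seq_len(nrow(counts)), counts$contrast)
  out <- do.call(rbind, lapply(sp, function(i) {
    ev <- sum(counts$events[i]); vs <- sum(counts$vesicles[i])
    tsec <- length(i) / freq
    amp <- if (ev > 0) vs / ev else NA_real_
    er <- ev / tsec
    data.frame(contrast = counts$contrast[i][1L],
               event_rate = er,
               mean_amplitude = amp,
               vesicle_rate = if (ev > 0) er * amp else 0)
  }))
  out <- out[order(out$contrast), ]
  rownames(out) <- NULL
  if (normalize_to == "lowest") {
    ok <- which(!is.na(out$mean_amplitude) & out$event_rate > 0)
    if (length(ok)) {
      ref <- ok[1L]
      out$relative_event_rate <- out$event_rate / out$event_rate[ref]
      out$relative_amplitude <- out$mean_amplitude / out$mean_amplitude[ref]
      out$relative_vesicle_rate <- out$vesicle_rate / out$vesicle_rate[ref]
    }
  }
  out
}

#' Probability density of event amplitudes, including empty cycles
#'
#' The distribution over response classes per stimulus cycle: the no-response
#' class (cycles with zero events) plus one class per event amplitude in
#' quanta. Each empty cycle and each event contributes one observation, so the
#' density sums to 1.
#'
#' @param counts a [count_per_cycle()] result.
#' @param series the [quantal_series()] the counts were built from.
#' @param protocol the matching protocol.
#' @return data frame with `class` (`"no_response"`, `"1"`, `"2"`, ...),
#'   `count`, `probability`.
#' @export
amplitude_distribution <- function(counts = NULL, series = NULL,
                                   protocol = NULL) {
  if (is.null(counts)) {
    stopifnot(!is.null(series), !is.null(protocol))
    counts <- count_per_cycle(series, protocol)
  }
  if (is.null(series)) stop("series is required to resolve event amplitudes")
  n_empty <- sum(counts$events == 0L)
  qt <- table(factor(series$quanta,
                     levels = seq_len(max(c(series$quanta, 1L)))))
  classes <- c("no_response", names(qt))
  cnt <- c(n_empty, as.integer(qt))
  tot <- sum(cnt)
  data.frame(class = classes, count = cnt,
             probability = if (tot > 0) cnt / tot else rep(0, length(cnt)))
}

#' Compare two amplitude distributions by a chi-squared test
#'
#' @param d1,d2 results of [amplitude_distribution()].
#' @return the `htest` object from [stats::chisq.test()] on the aligned count
#'   table.
#' @export
compare_amplitude_distributions <- function(d1, d2) {
  classes <- union(d1$class, d2$class)
  get <- function(d) {
    v <- stats::setNames(rep(0L, length(classes)), classes)
    v[d$class] <- d$count
    v
  }
  m <- rbind(get(d1), get(d2))
  m <- m[, colSums(m) > 0, drop = FALSE]
  suppressWarnings(stats::chisq.test(m))
}

#' Release rate as a function of stimulus frequency
#'
#' Classifies the frequency response of a synapse as low-pass or band-pass
#' from release rates measured at several stimulus frequencies. The response
#' is band-pass when an interior frequency's rate exceeds both endpoint rates
#' by at least the margin; otherwise low-pass. When a reference condition is
#' supplied, the relative gain (condition / reference) is reported per
#' frequency.
#'
#' @param rates data frame with columns `frequency` (Hz) and `rate`
#'   (vesicles/s), one row per frequency; or a list of [quantal_series()]
#'   named by frequency together with `durations`.
#' @param reference optional data frame of the same shape for the reference
#'   condition.
#' @param margin band-pass margin: the interior peak must exceed both endpoint
#'   rates by this factor minus one (default 1.2, i.e. 20%).
#' @param durations recording duration per frequency in seconds, when `rates`
#'   is a list of series.
#' @return a `frequency_response`: list with `table` (frequency, rate,
#'   optional relative_gain), `classification`.
#' @export
frequency_response <- function(rates, reference = NULL, margin = 1.2,
                               durations = NULL) {
  if (is.list(rates) && !is.data.frame(rates) &&
      all(vapply(rates, inherits, logical(1), "quantal_series"))) {
    stopifnot(!is.null(durations), length(durations) == length(rates))
    rates <- data.frame(
      frequency = as.numeric(names(rates)),
      rate = vapply(seq_along(rates),
                    function(i) sum(rates[[i]]$quanta) / durations[i],
                    numeric(1)))
  }
  rates <- as.data.frame(rates)
  stopifnot(all(c("frequency", "rate") %in% names(rates)))
  if (nrow(rates) < 3L)
    stop("frequency response needs >= 3 frequencies")
  rates <- rates[order(rates$frequency), ]
  if (any(diff(rates$frequency) <= 0))
    stop("frequencies must be distinct")
  r <- rates$rate
  k <- which.max(r)
  interior <- k > 1L && k < length(r)
  band <- interior && r[k] >= margin * r[1L] && r[k] >= margin * r[length(r)]
  if (!is.null(reference)) {
    reference <- as.data.frame(reference)
    m <- match(rates$frequency, reference$frequency)
    rates$relative_gain <- r / reference$rate[m]
  }
  structure(list(table = rates,
                 classification = if (band) "band-pass" else "low-pass",
                 margin = margin),
            class = "frequency_response")
}

#' @export
print.frequency_response <- function(x, ...) {
  cat(sprintf("Frequency response: %s (%d frequencies)\n",
              x$classification, nrow(x$table)))
  print(x$table)
  invisible(x)
}
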
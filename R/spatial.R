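#' Fit the spatial profile of a linescan as a sum of Gaussian point sources
#'
#' The time-averaged fluorescence profile along the scanned line is fitted
#' with a sum of Gaussians, each standing for one active zone. The number of
#' components (1 to `max_components`) is selected by the Bayesian information
#' criterion; components broader than the width criterion (full width at half
#' maximum of 1.5 um or more) are flagged as excluded from event analysis,
#' since wide profiles risk conflating several release sites.
#'
#' @param recording a `linescan_recording` (or any list with `values` matrix
#'   and `pixel_size`).
#' @param max_components maximum number of Gaussian components tried.
#' @param fwhm_limit exclusion threshold on the FWHM in micrometres
#'   (default 1.5); components at or above it are kept in the fit but marked
#'   `excluded`.
#' @return a `spatial_profile`: data frame `components` with columns
#'   `center`, `sigma`, `amplitude`, `fwhm`, `excluded`, plus `offset`,
#'   `residual_rms`, `n_components`, `bic` (per candidate count) and the
#'   fitted `profile`.
#' @export
fit_spatial_profile <- function(recording, max_components = 3L,
                                fwhm_limit = 1.5) {
  vals <- recording$values
  stopifnot(is.matrix(vals), nrow(vals) >= 8L)
  px <- recording$pixel_size
  x <- (seq_len(nrow(vals)) - 1L) * px
  y <- rowMeans(vals)
  n <- length(y)

  fits <- vector("list", max_components)
  bic <- rep(NA_real_, max_components)
  # peak seeding: local maxima of a lightly smoothed profile, tallest first
  ys <- stats::filter(y, rep(1 / 3, 3), sides = 2)
  ys[is.na(ys)] <- y[is.na(ys)]
  is_peak <- c(FALSE, diff(sign(diff(ys))) < 0, FALSE)
  peaks <- order(ys, decreasing = TRUE)
  peaks <- peaks[is_peak[peaks]]
  if (!length(peaks)) peaks <- which.max(ys)

  for (k in seq_len(max_components)) {
    centers0 <- x[peaks[seq_len(min(k, length(peaks)))]]
    if (length(centers0) < k)
      centers0 <- c(centers0,
                    seq(min(x), max(x), length.out = k + 2L)[2:(k + 1L)][
                      seq_len(k - length(centers0))])
    start <- list(b0 = min(y))
    lower <- c(b0 = -Inf); upper <- c(b0 = Inf)
    for (j in seq_len(k)) {
      start[[paste0("a", j)]] <- max(y) - min(y)
      start[[paste0("c", j)]] <- centers0[j]
      start[[paste0("s", j)]] <- 2 * px
      lower <- c(lower, stats::setNames(c(0, min(x), px / 4),
                                        paste0(c("a", "c", "s"), j)))
      upper <- c(upper, stats::setNames(c(Inf, max(x), diff(range(x))),
                                        paste0(c("a", "c", "s"), j)))
    }
    fml <- stats::as.formula(paste(
      "y ~ b0 +",
      paste(sprintf("a%d * exp(-(x - c%d)^2 / (2 * s%d^2))", 1:k, 1:k, 1:k),
            collapse = " + ")))
    fit <- tryCatch(
      minpack.lm::nlsLM(
        fml, data = data.frame(x = x, y = y),
        start = start, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    # floor the RSS at a tiny fraction of the profile scale: on noiseless
    # profiles the RSS collapses to numerical rounding and an unfloored BIC
    # would reward spurious extra components indefinitely
    rss <- max(rss, n * (1e-7 * max(abs(y)))^2)
    p <- 1L + 3L * k
    bic[k] <- n * log(rss / n) + p * log(n)
    fits[[k]] <- fit
  }
  ok <- which(!is.na(bic))
  if (!length(ok))
    stop("spatial profile fit failed to converge for any component count; ",
         "profile range = [", signif(min(y), 4), ", ", signif(max(y), 4), "]")
  kbest <- ok[which.min(bic[ok])]
  fit <- fits[[kbest]]
  cf <- stats::coef(fit)
  comp <- data.frame(
    center = unname(cf[paste0("c", seq_len(kbest))]),
    sigma = unname(cf[paste0("s", seq_len(kbest))]),
    amplitude = unname(cf[paste0("a", seq_len(kbest))]))
  comp <- comp[order(comp$center), , drop = FALSE]
  rownames(comp) <- NULL
  comp$fwhm <- 2 * comp$sigma * sqrt(2 * log(2))
  comp$excluded <- comp$fwhm >= fwhm_limit
  structure(list(components = comp,
                 offset = unname(cf[["b0"]]),
                 residual_rms = sqrt(mean(stats::residuals(fit)^2)),
                 n_components = kbest,
                 bic = bic,
                 positions = x,
                 profile = y,
                 fitted = stats::fitted(fit)),
            class = "spatial_profile")
}

#' @export
print.spatial_profile <- function(x, ...) {
  cat(sprintf("Spatial profile: %d Gaussian component(s), residual RMS %.4g\n",
              x$n_components, x$residual_rms))
  print(x$components)
  invisible(x)
}

#' Extract per-component fluorescence time series from a linescan
#'
#' With the component shapes fixed from the spatial fit, each time point of
#' the linescan is decomposed by linear least squares into a weighted sum of
#' the unit-peak component Gaussians (plus an optional flat offset). The
#' weight of component k at time t is its fluorescence F_k(t).
#'
#' @param recording a `linescan_recording`.
#' @param profile a [fit_spatial_profile()] result fitted on this recording's
#'   spatial axis.
#' @param include_offset include a spatially flat regressor (default TRUE).
#' @return a list of `fluorescence_trace` objects (one per component, excluded
#'   components included but flagged), each with fields `f` (a.u.), `line_rate`,
#'   `component` (row of the profile), `excluded`.
#' @export
extract_timeseries <- function(recording, profile, include_offset = TRUE) {
  stopifnot(inherits(profile, "spatial_profile"))
  vals <- recording$values
  x <- (seq_len(nrow(vals)) - 1L) * recording$pixel_size
  if (length(x) != length(profile$positions) ||
      max(abs(x - profile$positions)) > 1e-9)
    stop("profile was not fitted on this recording's spatial axis")
  comp <- profile$components
  G <- sapply(seq_len(nrow(comp)), function(j)
    exp(-(x - comp$center[j])^2 / (2 * comp$sigma[j]^2)))
  G <- matrix(G, nrow = length(x))
  # collinearity guard: near-identical component shapes make the solve
  # meaningless (checked among the Gaussians, before the flat offset column)
  if (ncol(G) > 1L) {
    cors <- suppressWarnings(stats::cor(G))
    diag(cors) <- 0
    bad <- which(!is.na(cors) & abs(cors) > 0.999, arr.ind = TRUE)
    if (nrow(bad)) {
      stop(sprintf(
        "spatial components %d and %d are nearly collinear; refit the profile",
        bad[1L, 1L], bad[1L, 2L]))
    }
  }
  if (include_offset) G <- cbind(G, 1)
  coefs <- qr.solve(G, vals)            # one QR, all time points at once
  coefs <- matrix(coefs, nrow = ncol(G))
  lapply(seq_len(nrow(comp)), function(j) {
    structure(list(f = as.numeric(coefs[j, ]),
                   line_rate = recording$line_rate,
                   component = comp[j, , drop = FALSE],
                   excluded = comp$excluded[j]),
              class = "fluorescence_trace")
  })
}

#' @export
print.fluorescence_trace <- function(x, ...) {
  cat(sprintf("Fluorescence trace: %d samples at %g Hz%s%s\n",
              length(x$f), x$line_rate,
              if (!is.null(x$f0)) sprintf(", F0 = %.4g", x$f0) else "",
              if (isTRUE(x$excluded)) " [excluded component]" else ""))
  invisible(x)
}
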
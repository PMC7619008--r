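#' Double-exponential reporter kernel
#'
#' Impulse response of the fluorescent glutamate reporter to a single release
#' event: an exponential decay gated by an exponential rise,
#' \deqn{h(t) = A \, e^{-t/\tau_f} (1 - e^{-t/\tau_r}), \quad t \ge 0,}
#' with `h(t) = 0` for `t < 0`. `tau_r` is the rise time constant and `tau_f`
#' the fall time constant. The kernel is zero at `t = 0` and peaks at
#' \eqn{t^* = \tau_r \log(1 + \tau_f/\tau_r)}.
#'
#' @param tau_r rise time constant in seconds (default 0.001 s).
#' @param tau_f fall time constant in seconds (default 0.06 s); must exceed
#'   `tau_r`.
#' @param A amplitude scale factor (default 1).
#' @return An object of class `glu_kernel` with fields `A`, `tau_r`, `tau_f`,
#'   `t_peak` (time of maximum) and `peak` (unscaled maximum of
#'   \eqn{e^{-t/\tau_f}(1-e^{-t/\tau_r})}).
#' @examples
#' k <- glu_kernel()
#' k$t_peak                      # ~ 4.1 ms
#' kernel_eval(k, c(0, k$t_peak))
#' @export
glu_kernel <- function(tau_r = 0.001, tau_f = 0.06, A = 1) {
  stopifnot(is.numeric(tau_r), is.numeric(tau_f), is.numeric(A),
            length(tau_r) == 1L, length(tau_f) == 1L, length(A) == 1L)
  if (!(tau_r > 0)) stop("tau_r must be > 0")
  if (!(tau_f > tau_r)) stop("tau_f must exceed tau_r")
  t_peak <- tau_r * log(1 + tau_f / tau_r)
  peak <- exp(-t_peak / tau_f) * (1 - exp(-t_peak / tau_r))
  structure(list(A = A, tau_r = tau_r, tau_f = tau_f,
                 t_peak = t_peak, peak = peak),
            class = "glu_kernel")
}

#' Evaluate a kernel at given times
#'
#' @param kernel a [glu_kernel()].
#' @param t times in seconds (vector); values `< 0` give 0.
#' @param normalize if `TRUE` (default `FALSE`), scale so the kernel peak is 1
#'   (the amplitude `A` is ignored).
#' @return numeric vector of kernel values.
#' @export
kernel_eval <- function(kernel, t, normalize = FALSE) {
  stopifnot(inherits(kernel, "glu_kernel"))
  h <- ifelse(t < 0, 0,
              exp(-t / kernel$tau_f) * (1 - exp(-t / kernel$tau_r)))
  if (normalize) h / kernel$peak else kernel$A * h
}

#' Sample a kernel on a regular time grid
#'
#' @param kernel a [glu_kernel()].
#' @param rate sampling rate in Hz (the linescan line rate).
#' @param duration length of the sampled kernel in seconds; default covers
#'   8 fall time constants, enough for the tail to decay below 3.4e-4 of peak.
#' @param normalize passed to [kernel_eval()].
#' @return numeric vector, kernel sampled at `0, 1/rate, 2/rate, ...`.
#' @export
kernel_sample <- function(kernel, rate, duration = 8 * kernel$tau_f,
                          normalize = TRUE) {
  stopifnot(rate > 0, duration > 0)
  t <- seq(0, duration, by = 1 / rate)
  kernel_eval(kernel, t, normalize = normalize)
}

#' @export
print.glu_kernel <- function(x, ...) {
  cat(sprintf(
    "Reporter kernel: tau_r = %g ms, tau_f = %g ms, A = %g (peak %.4g at %.3g ms)\n",
    1e3 * x$tau_r, 1e3 * x$tau_f, x$A, x$peak, 1e3 * x$t_peak))
  invisible(x)
}
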
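#' Build a contrast stimulus protocol
#'
#' A protocol is a sequence of full-field stimulus cycles, one contrast value
#' per cycle, delivered at a fixed temporal frequency. The canonical design is
#' 11 equiprobable contrasts spanning plus/minus 10% around the half-maximal
#' contrast of the synapse, modulated at 5 Hz (200-ms cycles), so the stimulus
#' entropy is log2(11) = 3.46 bits per cycle.
#'
#' @param contrast_set distinct percent-contrast values, each in \[0, 100\].
#' @param frequency stimulus frequency in Hz (default 5).
#' @param repeats number of cycles per contrast (default 1).
#' @param seed integer seed controlling the cycle order when `randomize` is
#'   `TRUE`.
#' @param randomize deliver contrasts in a seeded pseudo-random permutation
#'   (`TRUE`, default) or blockwise in the order given (`FALSE`).
#' @return A `stimulus_protocol`: list with `contrasts` (one per cycle),
#'   `frequency` (Hz), `cycle_duration` (s), `n_cycles`, `duration` (s) and
#'   `seed`.
#' @examples
#' p <- make_stimulus(seq(30, 50, by = 2), frequency = 5, repeats = 3, seed = 1)
#' stimulus_entropy(p)   # log2(11) = 3.46 bits per cycle
#' @export
make_stimulus <- function(contrast_set, frequency = 5, repeats = 1L,
                          seed = 1L, randomize = TRUE) {
  stopifnot(length(contrast_set) >= 1L, repeats >= 1L, frequency > 0)
  bad <- contrast_set[contrast_set < 0 | contrast_set > 100]
  if (length(bad))
    stop("contrast values outside [0, 100]: ", paste(bad, collapse = ", "))
  contrasts <- rep(contrast_set, each = repeats)
  if (randomize) {
    contrasts <- withr_seed(seed, sample(contrasts))
  }
  structure(list(contrasts = contrasts,
                 frequency = frequency,
                 cycle_duration = 1 / frequency,
                 n_cycles = length(contrasts),
                 duration = length(contrasts) / frequency,
                 seed = as.integer(seed)),
            class = "stimulus_protocol")
}

#' Entropy of the stimulus ensemble
#'
#' Shannon entropy H(S), in bits per cycle, of the empirical distribution of
#' contrasts in the protocol. For n equiprobable contrasts this is log2(n).
#'
#' @param protocol a [make_stimulus()] protocol.
#' @return entropy in bits per cycle.
#' @export
stimulus_entropy <- function(protocol) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  p <- table(protocol$contrasts) / protocol$n_cycles
  -sum(p * log2(p))
}

#' Cycle start times of a protocol
#' @param protocol a [make_stimulus()] protocol.
#' @return numeric vector of cycle start times in seconds (half-open cycles
#'   `[start, start + cycle_duration)`).
#' @export
cycle_starts <- function(protocol) {
  (seq_len(protocol$n_cycles) - 1L) * protocol$cycle_duration
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat(sprintf(
    "Stimulus protocol: %d cycles at %g Hz (%.3g s), %d distinct contrasts, H(S) = %.3f bits/cycle\n",
    x$n_cycles, x$frequency, x$duration,
    length(unique(x$contrasts)), stimulus_entropy(x)))
  invisible(x)
}

# Run expr under a local RNG seed without disturbing the caller's RNG state.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
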
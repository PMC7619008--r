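#' Write and read event tables
#'
#' Events are stored as plain CSV with columns `time_s`, `amplitude`,
#' `quanta`, `polarity`. Reading validates the schema and rejects
#' non-monotone times.
#'
#' @param series a [quantal_series()] (amplitudes taken from the attached
#'   train when present, else `quanta * quantal_amplitude`).
#' @param path file path.
#' @return `write_events` returns `path` invisibly; `read_events` returns a
#'   [quantal_series()] with the amplitudes attached as attribute
#'   `amplitudes`.
#' @export
write_events <- function(series, path) {
  stopifnot(inherits(series, "quantal_series"))
  train <- attr(series, "train")
  amp <- if (!is.null(train)) train$amplitudes
  else series$quanta * (series$quantal_amplitude %||% NA_real_)
  df <- data.frame(time_s = series$times,
                   amplitude = amp,
                   quanta = series$quanta,
                   polarity = rep(series$polarity,
                                  length.out = length(series$times)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "amplitude", "quanta", "polarity")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("event file missing column(s): ", paste(missing_cols, collapse = ", "))
  bad <- which(!is.finite(df$time_s) | !is.finite(df$quanta) |
                 df$quanta < 1)
  if (length(bad))
    stop("malformed event row(s) at line ", paste(bad + 1L, collapse = ", "))
  if (nrow(df) > 1L && any(diff(df$time_s) <= 0)) {
    ln <- which(diff(df$time_s) <= 0)[1L] + 2L
    stop("event times not strictly increasing at line ", ln)
  }
  pol <- if (nrow(df)) df$polarity[1L] else "unknown"
  qs <- quantal_series(df$time_s, df$quanta, polarity = pol)
  attr(qs, "amplitudes") <- df$amplitude
  qs
}

#' Write and read linescan recordings
#'
#' Recordings are stored as single-plane 32-bit float TIFF (position x time),
#' linearly rescaled to the unit interval, with a YAML sidecar (`<path>.yaml`)
#' holding the rescaling range, acquisition metadata (`line_rate_hz`,
#' `pixel_size_um`) and, when present, the simulation ground truth
#' (`truth_times`, `truth_quanta`).
#'
#' @param recording a `linescan_recording`.
#' @param path TIFF file path.
#' @return `write_linescan` returns `path` invisibly; `read_linescan` a
#'   `linescan_recording` (with ground truth re-attached when present).
#' @export
write_linescan <- function(recording, path) {
  stopifnot(inherits(recording, "linescan_recording"))
  v <- recording$values
  rng <- range(v)
  scaled <- if (diff(rng) > 0) (v - rng[1L]) / diff(rng) else v * 0
  tiff::writeTIFF(scaled, path, bits.per.sample = 32L)
  meta <- list(line_rate_hz = recording$line_rate,
               pixel_size_um = recording$pixel_size,
               value_min = rng[1L], value_max = rng[2L])
  truth <- attr(recording, "truth")
  if (!is.null(truth)) {
    meta$truth_times <- as.numeric(truth$times)
    meta$truth_quanta <- as.integer(truth$quanta)
    meta$truth_quantal_amplitude <- truth$quantal_amplitude
  }
  yaml::write_yaml(meta, paste0(path, ".yaml"), precision = 15L)
  invisible(path)
}

#' @rdname write_linescan
#' @export
read_linescan <- function(path) {
  meta_path <- paste0(path, ".yaml")
  if (!file.exists(meta_path))
    stop("metadata sidecar not found: ", meta_path)
  meta <- yaml::read_yaml(meta_path)
  scaled <- tiff::readTIFF(path)
  v <- scaled * (meta$value_max - meta$value_min) + meta$value_min
  rec <- structure(list(values = v,
                        line_rate = meta$line_rate_hz,
                        pixel_size = meta$pixel_size_um,
                        duration = ncol(v) / meta$line_rate_hz,
                        positions = (seq_len(nrow(v)) - 1L) * meta$pixel_size_um),
                   class = "linescan_recording")
  if (!is.null(meta$truth_times)) {
    attr(rec, "truth") <- quantal_series(
      unlist(meta$truth_times), unlist(meta$truth_quanta),
      quantal_amplitude = meta$truth_quantal_amplitude %||% NA_real_)
  }
  rec
}

#' Write a plain dF/F0 trace as CSV (time, dff)
#' @param trace a baseline-corrected trace (field `dff`).
#' @param path file path.
#' @export
write_trace <- function(trace, path) {
  t <- (seq_along(trace$dff) - 1L) / trace$line_rate
  utils::write.csv(data.frame(time_s = t, dff = trace$dff), path,
                   row.names = FALSE)
  invisible(path)
}

#' Read a plain dF/F0 trace CSV, entering the pipeline at deconvolution
#' @param path CSV with columns `time_s`, `dff` on a regular grid.
#' @return a `fluorescence_trace` with `dff` and inferred `line_rate`.
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("time_s", "dff") %in% names(df)))
  dt <- diff(df$time_s)
  if (max(abs(dt - dt[1L])) > 1e-6 * dt[1L])
    stop("trace time axis is not regular")
  structure(list(dff = df$dff, line_rate = 1 / dt[1L]),
            class = "fluorescence_trace")
}
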
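#' Load and validate a pipeline configuration
#'
#' A single YAML file drives all stages. Recognized top-level keys:
#' `condition` (free-text label), `seed`, `out_dir`, and the per-stage blocks
#' `stimulus` (contrast_set, frequency, repeats, randomize), `release`
#' (base_rate, rate_gain or r_max/c_half/hill_n, quantal_amplitude,
#' mvr_weights, amplitude_cv), `kernel` (tau_r, tau_f), `imaging`
#' (n_positions, pixel_size, line_rate, source_centers, source_widths,
#' noise_sd, bleach_slope, baseline_F0), `detect` (threshold_sd, refractory,
#' noise_power, cv, max_components), `info` (bin_width, aggregation), `input`
#' (path of an existing recording, skipping simulation). Unknown keys are
#' rejected.
#'
#' @param path YAML file, or a list already in that shape.
#' @return validated config list of class `pipeline_config`.
#' @export
load_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  known <- c("condition", "seed", "out_dir", "stimulus", "release", "kernel",
             "imaging", "detect", "info", "input")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(cfg$seed)) stop("config must set an explicit seed")
  if (is.null(cfg$kernel)) stop("config must define the kernel block")
  if (is.null(cfg$stimulus)) stop("config must define the stimulus block")
  cfg$condition <- cfg$condition %||% "unlabelled"
  structure(cfg, class = "pipeline_config")
}

config_kernel <- function(cfg)
  glu_kernel(tau_r = cfg$kernel$tau_r %||% 0.001,
             tau_f = cfg$kernel$tau_f %||% 0.06)

config_protocol <- function(cfg) {
  s <- cfg$stimulus
  make_stimulus(unlist(s$contrast_set), frequency = s$frequency %||% 5,
                repeats = s$repeats %||% 1L, seed = cfg$seed,
                randomize = s$randomize %||% TRUE)
}

#' Run the full pipeline from a configuration
#'
#' Executes, in order: simulate (skipped when `input` points at an existing
#' recording), quantal decomposition (detect), response analysis and the
#' information report, writing each stage's outputs under `out_dir` and a run
#' manifest (`manifest.yaml`) with the config hash, package version and
#' per-file checksums. A stage failure aborts with the failing stage named;
#' outputs of completed stages are preserved.
#'
#' @param config path to a YAML config or a [load_config()] result.
#' @param out_dir output directory (overrides the config's `out_dir`).
#' @return the manifest, invisibly; stage outputs on disk and in the returned
#'   attribute `results`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (inherits(config, "pipeline_config")) config else load_config(config)
  out_dir <- out_dir %||% cfg$out_dir %||% stop("no out_dir configured")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  kernel <- config_kernel(cfg)
  protocol <- config_protocol(cfg)

  rec_path <- file.path(out_dir, "recording.tif")
  if (!is.null(cfg$input)) {
    if (!file.exists(cfg$input)) stop("input recording not found: ", cfg$input)
    recording <- stage("load", read_linescan(cfg$input))
  } else {
    recording <- stage("simulate", {
      r <- cfg$release
      model <- release_model(
        base_rate = r$base_rate %||% 0,
        rate_gain = r$rate_gain %||% 0,
        r_max = r$r_max, c_half = r$c_half, hill_n = r$hill_n,
        quantal_amplitude = r$quantal_amplitude %||% 0.5,
        mvr_weights = unlist(r$mvr_weights) %||% 1,
        amplitude_cv = r$amplitude_cv %||% 0)
      im <- cfg$imaging %||% list()
      imaging <- imaging_model(
        n_positions = im$n_positions %||% 32L,
        pixel_size = im$pixel_size %||% 0.25,
        line_rate = im$line_rate %||% 1000,
        source_centers = unlist(im$source_centers) %||% 4,
        source_widths = unlist(im$source_widths) %||% 0.4,
        noise_sd = im$noise_sd %||% 0.05,
        bleach_slope = im$bleach_slope %||% 0,
        baseline_F0 = im$baseline_F0 %||% 100)
      rec <- simulate_recording(protocol, model, kernel, imaging,
                                seed = cfg$seed)
      write_linescan(rec, rec_path)
      rec
    })
  }
  results$recording <- recording

  det <- cfg$detect %||% list()
  series_list <- stage("detect",
    decompose_recording(recording, kernel,
                        threshold_sd = det$threshold_sd %||% 3.5,
                        refractory = det$refractory %||% 0.005,
                        noise_power = det$noise_power %||% "auto",
                        cv = det$cv %||% 0.15,
                        max_components = det$max_components %||% 3L))
  if (!length(series_list))
    stop("pipeline stage 'detect' failed: no retained spatial components")
  series <- series_list[[1L]]
  ev_path <- file.path(out_dir, "events.csv")
  write_events(series, ev_path)
  results$series <- series

  results$response <- stage("respond", {
    counts <- count_per_cycle(series, protocol)
    resp <- list(counts = counts,
                 rates = release_rate_per_contrast(counts),
                 factorization = tryCatch(factorize_code(counts),
                                          error = function(e) NULL),
                 hill = tryCatch(fit_hill(counts), error = function(e) NULL))
    if (!is.null(resp$hill))
      resp$gain <- tryCatch(contrast_gain(counts, resp$hill$c_half),
                            error = function(e) NULL)
    utils::write.csv(resp$rates, file.path(out_dir, "rates.csv"),
                     row.names = FALSE)
    resp
  })

  results$info <- stage("info", {
    icfg <- cfg$info %||% list()
    rep <- information_report(series, protocol,
                              bin_width = icfg$bin_width %||% 0.02,
                              aggregation = icfg$aggregation %||% "sum_bins")
    sn <- tryCatch(snr(results$response$counts),
                   error = function(e) NULL)
    jsonlite::write_json(
      list(H_S = rep$H_S,
           I_bits_per_bin = rep$I_bits_per_bin,
           I_bits_per_cycle = rep$I_bits_per_cycle,
           I_bits_per_s = rep$I_bits_per_s,
           I2_per_q = rep$specific,
           violation_rate = rep$violation_rate,
           SNR_per_contrast = sn),
      file.path(out_dir, "info.json"), auto_unbox = TRUE, digits = NA)
    rep
  })

  manifest <- build_manifest(cfg, out_dir)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  attr(manifest, "results") <- results
  invisible(manifest)
}

# Manifest: config hash + md5 of every regular output file.
build_manifest <- function(cfg, out_dir) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(cfg), tmp)
  cfg_hash <- unname(tools::md5sum(tmp))
  files <- setdiff(list.files(out_dir, full.names = TRUE),
                   file.path(out_dir, "manifest.yaml"))
  files <- files[!dir.exists(files)]
  sums <- tools::md5sum(files)
  list(config_hash = cfg_hash,
       package_version = as.character(utils::packageVersion("quantalglu")),
       condition = cfg$condition,
       seed = cfg$seed,
       files = as.list(stats::setNames(unname(sums), basename(files))),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}
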
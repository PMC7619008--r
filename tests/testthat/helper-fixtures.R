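# Shared fixture builders for the test suite. Everything is generated in code
# from explicit seeds; nothing is read from disk.

# The canonical stimulus design: 11 equiprobable contrasts spanning +/-10%
# around a 40% half-maximal contrast, 5 Hz.
standard_protocol <- function(repeats = 4L, seed = 7L, randomize = TRUE) {
  make_stimulus(seq(30, 50, by = 2), frequency = 5, repeats = repeats,
                seed = seed, randomize = randomize)
}

standard_model <- function(amplitude_cv = 0, mvr = c(0.6, 0.3, 0.1)) {
  release_model(base_rate = 0, r_max = 10, c_half = 40, hill_n = 3,
                quantal_amplitude = 0.5, mvr_weights = mvr,
                amplitude_cv = amplitude_cv)
}

quiet_imaging <- function(noise_sd = 0.01, bleach = 0.002) {
  imaging_model(n_positions = 24L, pixel_size = 0.25, line_rate = 1000,
                source_centers = 3, source_widths = 0.4,
                noise_sd = noise_sd, bleach_slope = bleach,
                baseline_F0 = 100)
}

# A trace already in dF/F0 units, entering the pipeline at deconvolution.
sim_trace_dff <- function(dff, rate = 1000) {
  structure(list(dff = dff, line_rate = rate),
            class = "fluorescence_trace")
}

# Match detected events to ground truth within a time tolerance; returns
# recall, precision and the fraction of matched events whose quantal
# assignment agrees with truth.
match_events <- function(detected, truth, tol = 0.005) {
  recall <- if (length(truth$times))
    mean(vapply(truth$times,
                function(t) any(abs(detected$times - t) < tol), logical(1)))
  else NA_real_
  idx <- vapply(detected$times, function(t) {
    d <- abs(truth$times - t)
    if (length(d) && min(d) < tol) which.min(d) else NA_integer_
  }, integer(1))
  precision <- if (length(idx)) mean(!is.na(idx)) else NA_real_
  ok <- !is.na(idx)
  acc <- if (any(ok)) mean(detected$quanta[ok] == truth$quanta[idx[ok]])
  else NA_real_
  list(recall = recall, precision = precision, quantal_accuracy = acc)
}

# Independent brute-force mutual information oracle: plain double loop over
# the joint table, never touching the package's estimator internals.
mi_oracle <- function(p_q_given_s, p_s) {
  joint <- p_q_given_s * p_s
  pq <- colSums(joint)
  total <- 0
  for (i in seq_len(nrow(joint))) {
    for (j in seq_len(ncol(joint))) {
      if (joint[i, j] > 0)
        total <- total + joint[i, j] *
          log2(joint[i, j] / (p_s[i] * pq[j]))
    }
  }
  total
}

# Random conditional table with Dirichlet(1) rows.
random_channel <- function(n_s, n_q, seed) {
  set.seed(seed)
  m <- matrix(stats::rexp(n_s * n_q), n_s, n_q)
  m / rowSums(m)
}
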
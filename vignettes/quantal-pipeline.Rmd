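---
title: "From linescan fluorescence to quantal release and information transmission"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From linescan fluorescence to quantal release and information transmission}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quantalglu)
```

## The measurement problem

A fluorescent glutamate reporter expressed at the synaptic terminals of
retinal bipolar cells converts vesicle fusion into optical transients. A
linescan — a single scan line swept across the terminal at ~1 kHz — yields a
position x time image in which each active zone appears as a Gaussian-shaped
stripe whose brightness fluctuates as vesicles release glutamate. Because
two or more vesicles can fuse synchronously (multivesicular release, MVR),
the transients come in integer multiples of a unitary amplitude, the quantum.

`quantalglu` turns such recordings into (i) a time series of release events
with integer vesicle counts, and (ii) the downstream physiology: the
contrast-response function and its half-maximal contrast C1/2, the maximum
contrast gain, the rate-versus-amplitude factorization of the vesicle code,
the trial-to-trial signal-to-noise ratio, and the mutual and specific
information between stimulus contrast and the quantal response.

## The decomposition pipeline

Six stages, mirroring how such data are analysed in practice:

1. **Spatial decomposition** (`fit_spatial_profile`). The time-averaged
   profile along the line is fitted with a sum of Gaussians, each a point
   source standing for one active zone. The number of components is chosen
   by BIC over 1..`max_components`; a floor on the residual sum of squares
   (1e-7 of the profile scale, squared) keeps BIC from rewarding spurious
   components on noiseless synthetic profiles. Components with a full width
   at half maximum of 1.5 um or more are flagged and excluded from event
   analysis: so wide a profile risks conflating neighbouring release sites.
2. **Time-series extraction** (`extract_timeseries`). With shapes fixed,
   each time point is decomposed by one QR-based linear solve into component
   weights (plus a flat offset). Nearly collinear components (|r| > 0.999)
   are refused by name rather than silently inverted.
3. **Baseline correction** (`correct_baseline`). Bleaching is removed as a
   linear trend fitted with a redescending (bisquare) M-estimator, which
   ignores the one-sided release transients that would tilt an ordinary
   least-squares line by ~10% in typical traces. F0 is the mode of the
   corrected trace — the most frequent value, not the mean, because activity
   skews the distribution upward — estimated as the maximum of a Gaussian
   kernel density with Silverman's bandwidth (a histogram mode is the
   documented fallback). The output is dF/F0.
4. **Wiener deconvolution** (`wiener_deconvolve`). Release events are
   identified by their stereotyped kinetics, the double-exponential kernel
   `h(t) = A exp(-t/tau_f) (1 - exp(-t/tau_r))` with defaults tau_r = 1 ms,
   tau_f = 60 ms — an exponential fall with time constant tau_f gated by an
   exponential rise with time constant tau_r (this form is sometimes typeset
   with the rise constant repeated in both factors; here the fall factor
   uses tau_f, matching the meaning of the two constants). The
   frequency-domain Wiener estimate divides out the kernel while damping
   frequencies where noise dominates; the noise-to-signal ratio is estimated
   from the power spectrum above 250 Hz, where the kernel passes essentially
   nothing.
5. **Event extraction** (`detect_events`). Events are local maxima of the
   deconvolved trace above `threshold_sd` (default 3.5, the middle of the
   conventional 3-4 SD range) robust standard deviations (MAD x 1.4826,
   so the events themselves do not inflate the estimate). Plateau ties break
   to the earliest sample; a 5-ms refractory window suppresses secondary
   maxima of one impulse, keeping detection monotone in the threshold.
   *Amplitude readout.* Events are timed at the local maximum, but the
   amplitude is, by default, the sum of the deconvolved trace over a +/-3 ms
   window around it. For events falling between samples the raw sample
   maximum fluctuates by 20-30% (CV) with the sub-sample phase even in
   noiseless data — enough to wash out the quantal clusters — whereas the
   windowed sum is phase-invariant (CV ~0.3% noiseless) and equals the
   event's peak dF/F0 for an ideal linear deconvolution. `amplitude =
   "peak"` restores the raw-maximum readout. In integral mode, candidates
   whose summed amplitude stays within the noise scale are discarded: noise
   wiggles integrate to ~0 because the filter's side lobes cancel, while
   real impulses carry their mass.
6. **Quantal clustering** (`cluster_quanta`). Amplitudes are partitioned
   into integer multiples of a unit q by maximum likelihood under a Gaussian
   mixture centred at k*q. The search is anchored at the first mode of the
   amplitude density (univesicular events are the most common class); a free
   ML search is degenerate because q/2 with doubled indices scores at least
   as well whenever the component spread scales with q. The anchor is then
   polished by soft EM in which q solves the responsibility-weighted least
   squares — solving for q by least squares rather than joint ML avoids the
   O(cv^2) downward bias that the q-tied spread puts on the likelihood. Two
   spread models are available: `"sqrt_k"` (default; component SD grows as
   sqrt(k), variance additivity of independent quanta) and `"fixed"`. Events
   are assigned k = round(a/q), floored at 1. Fewer than 10 events cannot
   support estimation and require an explicit `quantal_amplitude`.

ON/OFF polarity (`classify_polarity`) is read from 1-s steps of positive and
negative contrast at the start of a recording: the rate in one window must
exceed 1.5x the other, otherwise the polarity is `unknown` rather than a
forced call.

## Response measures

`count_per_cycle` assigns events to stimulus cycles by half-open intervals
and tallies vesicles, events and mean amplitude per cycle. From there:

- `fit_hill`: mean vesicles/cycle vs contrast fitted with
  `r(c) = r_max c^n / (c^n + C1/2^n)` by bounded Levenberg-Marquardt,
  weighted by reciprocal mean (Poisson-like variance) and multistarted over
  a small (C1/2, n) grid; without the weights and restarts a few percent of
  noisy fits run into the parameter bounds and skew the C1/2 distribution.
  Bounds: n in [0.5, 8], C1/2 in (1, 100]. Decreasing data are flagged, not
  fitted silently.
- `contrast_gain`: the slope of release rate vs contrast over
  C1/2 +/- 10%, after normalizing to the rate at the window's lowest
  contrast. The window must hold at least 3 measured contrasts.
- `factorize_code`: vesicle rate = event rate x mean event amplitude,
  an identity by construction at every contrast (empty cycles contribute
  zero rate and are excluded from the amplitude mean). This separates gain
  carried by firing more events from gain carried by MVR. The relation is
  sometimes written as a quotient; the product is the dimensionally
  consistent form and is what is implemented.
- `amplitude_distribution`: the probability distribution over response
  classes per cycle (no-response, 1, 2, ... quanta), comparable across
  conditions by `compare_amplitude_distributions` (chi-squared).
- `frequency_response`: low-pass vs band-pass classification; band-pass
  requires an interior peak exceeding both endpoint rates by 20% (the
  literature classifies qualitatively; the margin makes the call testable).

## SNR and information

`snr` implements SNR = S^2/sigma^2 per contrast, with S the trial-mean
vesicles per cycle and sigma^2 the across-trial variance (unbiased n-1
estimator by default, configurable; the choice is not prescribed by
convention). Zero variance yields a flagged infinite SNR, not an error.

`bin_events` discretizes the quantal series into 20-ms bins aligned to the
(200-ms) cycles — the bin width must divide the cycle — so that each bin
holds 0 or one event's quanta; bins with two events have their quanta summed
into one symbol and are flagged, and the violation rate is reported (at
20 ms it should be rare; a high rate means the bin width is too coarse for
the firing rate).

`estimate_distributions` builds the plug-in tables: p(Q|S) by empirical
frequency within each contrast, p(S) taken from the designed protocol
(exactly uniform for an equiprobable design, rather than re-estimated),
p(S,Q) = p(Q|S)p(S), p(Q), and p(S|Q) = p(S,Q)/p(Q). `mutual_information`
computes the double sum with base-2 logarithms and 0 log 0 = 0;
`specific_information` computes I2(S;q) = H(S) - H(S|q), whose p(q)-weighted
mean is the mutual information (individual values may be negative). No bias
correction is applied by default — the plug-in estimator is the convention
this pipeline follows — but `shuffle_null_information` estimates the
small-sample bias by destroying the stimulus-response association. The
plug-in estimate has the expected positive small-sample bias, shrinking as
bins accumulate.

Per-cycle information is, by default, the per-bin information times the
bins per cycle (`aggregation = "sum_bins"`), which treats bins as
conditionally independent symbols; `"cycle_symbol"` instead takes the total
quanta per cycle as one symbol. The summation reading matches how per-cycle
rates are usually quoted and is the default; both are one config key apart
because the published wording supports either. `information_rate` converts
bits/cycle to bits/s (log2(11) = 3.46 bits per 200-ms cycle is 17.3 bits/s
at 5 Hz).

## The synthetic generator

`make_stimulus` + `release_model` + `glu_kernel` + `imaging_model` +
`simulate_recording` generate linescans with known ground truth:

- The canonical protocol is 11 equiprobable contrasts spanning +/-10% around
  the synapse's C1/2, 5 Hz, pseudo-random order under an explicit seed.
- Event counts per cycle are Poisson at rate(contrast) (linear or
  Hill-saturating); event times are uniform within the cycle (homogeneous
  Poisson — no within-cycle phase structure is assumed), with a phase-locked
  option for realism. `min_separation` thins events to a minimum gap when
  isolated transients are wanted.
- Quanta per event are drawn from the MVR mixture `mvr_weights`; the
  rendered amplitude of a k-quantum event is Normal(k q, (cv q)^2) — the
  single-quantum coefficient of variation applies to the packet.
- Rendering: each source contributes a unit-peak spatial Gaussian times
  `F0 (1 - bleach_slope t)(1 + dF/F0(t))`, with the dF/F0 trace a
  superposition of peak-normalized kernels scaled by event amplitudes;
  additive Gaussian noise (optionally shot-like, variance scaling with
  signal) in dF/F0 units times F0; bleaching is linear because that is the
  correction the analysis applies.
- All randomness flows from explicit seeds; identical inputs and seed give
  bit-identical recordings.

What the generator does **not** emulate: optical point-spread blur beyond
the source Gaussians, scan jitter and motion, reporter saturation and
nonlinearity, dark/spontaneous events with distinct kinetics, correlated
(pink) noise, and release re-depression dynamics. Passing round-trip tests
therefore demonstrates that the analysis inverts its own forward model at
realistic SNR — a necessary condition — not that it is robust to every
artefact of in vivo imaging.

## Numerical choices and problem sizes

- Default kernel tau_r = 1 ms, tau_f = 60 ms; kernel sampled over 8 tau_f.
- Wiener noise floor from the >250 Hz spectral tail; explicit `noise_power`
  overrides.
- Detection threshold 3.5 robust SDs; refractory 5 ms; integral amplitude
  window +/-3 ms. A noiseless trace has its noise scale floored at 1e-9 of
  the signal so deconvolution rounding never counts as events.
- Quantal clustering: CV default 0.15; up to 10 quanta per event.
- Hill bounds as above; gain window half-width 10% contrast.
- Verification sizes (chosen to make Monte-Carlo error a small fraction of
  each tolerance): round-trip recovery on ~60 s of 1 kHz linescan
  (~150 events); Hill recovery on 100 replicates of 30 cycles/contrast;
  the 8-fold gain-ratio comparison on 500 cycles/contrast per replicate, as
  for a pooled population of synapses, because the shallower slope is
  otherwise below the Poisson noise floor; information oracle checks on 100
  random 4x4 channels.

## A worked example

```{r example, eval = FALSE}
protocol <- make_stimulus(seq(30, 50, 2), frequency = 5, repeats = 27,
                          seed = 1)
model <- release_model(base_rate = 0.5, r_max = 10, c_half = 40, hill_n = 3,
                       quantal_amplitude = 0.5,
                       mvr_weights = c(0.5, 0.3, 0.2), amplitude_cv = 0.15)
rec <- simulate_recording(protocol, model,
                          imaging = imaging_model(noise_sd = 0.02),
                          seed = 1)
series <- decompose_recording(rec)[[1]]

counts <- count_per_cycle(series, protocol)
fit <- fit_hill(counts)
gain <- contrast_gain(counts, fit$c_half)
info <- information_report(series, protocol)
snr_tab <- snr(counts)
```

## Known limitations

- Overlapping events closer than the refractory window merge; the pipeline
  reports the merged amplitude rather than attempting sub-refractory
  splitting.
- The quantal unit is assumed stationary within a recording; slow rundown
  of the unitary amplitude would blur the clusters.
- The plug-in information estimator is biased upward at small sample sizes;
  use the shuffle diagnostic before comparing conditions with very
  different cycle counts.
- `fit_spatial_profile` seeds component centres from smoothed profile peaks;
  heavily overlapping sources (< ~1 um apart at sigma 0.4 um) may resolve
  as one flagged wide component instead of two.
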
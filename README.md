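# quantalglu

Quantal decomposition and information analysis of glutamate-imaging
linescans from ribbon synapses.

Bipolar cells of the retina transmit the visual signal to the inner retina
by releasing glutamate in discrete packets — single vesicles, or several
fused synchronously (multivesicular release). A fluorescent glutamate
reporter imaged by two-photon linescan at ~1 kHz turns each release event
into a stereotyped optical transient, so a recording at one synapse is a
position x time image containing a train of quantized events. This package
reconstructs that train and quantifies how the synapse encodes stimulus
contrast, for anyone analysing such recordings (or building detection
methods against simulated ones).

## What it computes

**Event detection** (the quantal decomposition): the time-averaged spatial
profile is decomposed into Gaussian point sources (active zones); each
source's fluorescence time series is extracted by linear least squares,
bleach-corrected and converted to dF/F0 with the baseline F0 taken as the
mode of the trace; release events are recovered by Wiener deconvolution
against the reporter kernel

    h(t) = A exp(-t / tau_f) (1 - exp(-t / tau_r)),   tau_r = 1 ms, tau_f = 60 ms,

thresholded at 3.5 robust SDs, and partitioned into integer numbers of
quanta by a maximum-likelihood mixture over integer multiples of the
unitary amplitude q.

**Response measures**: per-cycle vesicle counts; the contrast-response
function r(c) = r_max c^n / (c^n + C1/2^n) and its half-maximal contrast
C1/2; the maximum contrast gain (slope of normalized release rate over
C1/2 +/- 10%); the factorization vesicle rate = event rate x event
amplitude; the amplitude distribution including empty cycles; low-pass vs
band-pass frequency response.

**Signal and information**: the trial-to-trial SNR = S^2/sigma^2 per
contrast; and, from 20-ms binned responses, the plug-in mutual information
I(S;Q) = H(S) - H(S|Q) between stimulus contrast and quantal response,
together with the specific information I2(S;q) = H(S) - H(S|q) carried by
each symbol (its p(q)-weighted mean is I).

A synthetic-recording generator with known ground truth (Poisson release
with contrast-dependent rate, an MVR mixture, the double-exponential
kernel, Gaussian sources, noise and linear bleaching) makes the whole
pipeline testable end to end.

## A worked example

Estimate C1/2 from a wide contrast-response protocol, then probe the
synapse with 11 contrasts spanning +/-10% around it — the design used for
gain and information measurements:

```r
library(quantalglu)

model <- release_model(base_rate = 0.3, r_max = 5, c_half = 40, hill_n = 3,
                       quantal_amplitude = 0.5,
                       mvr_weights = c(0.5, 0.3, 0.2), amplitude_cv = 0.15)

cr_protocol <- make_stimulus(seq(10, 100, by = 10), frequency = 5,
                             repeats = 30, seed = 1)
cr_rec <- simulate_recording(cr_protocol, model,
                             imaging = imaging_model(noise_sd = 0.02),
                             seed = 1)
cr_series <- decompose_recording(cr_rec)[[1]]
fit <- fit_hill(count_per_cycle(cr_series, cr_protocol))
fit
#> Hill contrast-response fit: r_max = 2.15 vesicles/cycle,
#>   C1/2 = 53.4% (95% CI 21.3-85.6), n = 2.55

protocol <- make_stimulus(seq(43, 63, 2), frequency = 5, repeats = 27,
                          seed = 2)
rec <- simulate_recording(protocol, model,
                          imaging = imaging_model(noise_sd = 0.02), seed = 2)
series <- decompose_recording(rec)[[1]]
counts <- count_per_cycle(series, protocol)

contrast_gain(counts, fit$c_half)
#> Contrast gain: slope 0.01818 (relative rate per % contrast)
#>   over [43.4, 63.4]%, normalized at 45%

information_report(series, protocol)
#> Information report (sum_bins): 0.009753 bits/bin, 0.09753 bits/cycle,
#>   0.4876 bits/s (H(S) = 3.459 bits)

head(snr(counts), 3)
#>   contrast         S   sigma2       snr n_trials degenerate
#> 1       43 0.6666667 1.461538 0.3040936       27      FALSE
#> 2       45 1.0740741 1.686610 0.6839965       27      FALSE
#> 3       47 1.0000000 2.923077 0.3421053       27      FALSE
```

Reading the numbers: the single-synapse C1/2 has a wide confidence interval
(the generating model used C1/2 = 40%; population estimates pool many
synapses); the gain slope of ~0.018 per % contrast means the release rate
roughly doubles over the 20% window; the synapse transmits ~0.49 bits/s of
the 17.3 bits/s available in the stimulus ensemble, and per-contrast SNRs
are well below 1 — single synapses are noisy channels, which is exactly why
the information-theoretic summary is the right lens.

The stimulus set itself carries `stimulus_entropy(protocol)` = log2(11) =
3.46 bits per 200-ms cycle, i.e. 17.3 bits/s at 5 Hz.

## Command line

A thin CLI over the same functions lives at `inst/cli/quantalglu.R`:

```sh
Rscript inst/cli/quantalglu.R run --config inst/extdata/demo-config.yaml --out demo_out
Rscript inst/cli/quantalglu.R detect --in demo_out/recording.tif --threshold 3.5 --out demo_out
```

`simulate`, `detect`, `respond`, `info` and `run` are available; a single
YAML config drives all stages (see `inst/extdata/demo-config.yaml`), CLI
flags override config values, and every run writes a manifest with config
hash and output checksums.

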
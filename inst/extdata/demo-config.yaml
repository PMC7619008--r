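# Demo pipeline configuration: one synthetic synapse, 11-contrast protocol
# around a half-maximal contrast of 40%, 5 Hz modulation at 1 kHz line rate.
condition: demo
seed: 42
out_dir: quantalglu_demo
stimulus:
  contrast_set: [30, 32, 34, 36, 38, 40, 42, 44, 46, 48, 50]
  frequency: 5
  repeats: 4
  randomize: true
release:
  base_rate: 0.5
  r_max: 12
  c_half: 40
  hill_n: 3
  quantal_amplitude: 0.5
  mvr_weights: [0.6, 0.3, 0.1]
  amplitude_cv: 0.0
kernel:
  tau_r: 0.001
  tau_f: 0.06
imaging:
  n_positions: 24
  pixel_size: 0.25
  line_rate: 1000
  source_centers: [3.0]
  source_widths: [0.4]
  noise_sd: 0.01
  bleach_slope: 0.002
  baseline_F0: 100
detect:
  threshold_sd: 3.5
  refractory: 0.005
info:
  bin_width: 0.02
  aggregation: sum_bins
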
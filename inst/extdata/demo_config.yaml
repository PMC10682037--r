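# Demonstration pipeline configuration: one high-level visual model and
# one correlated semantic-style model injected into a posterior region,
# with lagged feedforward coupling to an anterior region.
seed: 1
n_subjects: 10
models:
- name: visual
  n_items: 20
  n_features: 40
  family: continuous-activation
  seed: 11
- name: semantic
  n_items: 20
  n_features: 40
  family: continuous-activation
  correlation_to: visual
  target_rho: 0.3
  seed: 22
regions:
- name: posterior
  n_channels: 10
- name: anterior
  n_channels: 10
injections:
- model: visual
  region: posterior
  onset_ms: 80.0
  duration_ms: 160.0
  snr: 2.0
- model: semantic
  region: posterior
  onset_ms: 180.0
  duration_ms: 160.0
  snr: 1.5
couplings:
- source_region: posterior
  target_region: anterior
  lag_ms: 10.0
  gain: 0.8
  model: visual
epoch_window_ms: [-100.0, 400.0]
sampling_rate_hz: 200.0
noise_sd: 1.0
analysis:
  window_ms: 40
  alpha_forming: 0.01
  n_permutations: 1000
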
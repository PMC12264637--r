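# Default experiment configuration (all values equal the package defaults;
# any key may be omitted). Used as: auscultate.R run --config experiment.yaml
n_healthy: 35
n_unhealthy: 77
frame_s: 2.5
hop_s: 1.25
hidden: [30, 20]
fractions: [0.70, 0.15, 0.15]
seed: 42
mfcc:
  n_mels: 26
  n_coeffs: 13
  win_s: 0.025
  hop_s: 0.010
  log_floor: 1.0e-10
training:
  eta: 0.01
  max_epochs: 10000
  patience: 1000
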
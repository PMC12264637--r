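---
title: "Classifying lung sounds with stethoscope-mode features and an MLP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying lung sounds with stethoscope-mode features and an MLP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Auscultation — listening to lung sounds through a stethoscope — remains a
first-line diagnostic for pulmonary disease, but its interpretation is
subjective. Electronic stethoscopes record the sound, which opens the door to
automated screening: label a recording *healthy* or *unhealthy* (the latter
pooling conditions such as asthma, COPD, pneumonia, bronchitis, heart
failure, fibrosis and pleural effusion). `auscultate` implements a complete,
reproducible pipeline for this binary task:

1. **Preprocess** each recording under the three electronic-stethoscope
   filter modes — Bell (20–200 Hz), Diaphragm (100–500 Hz), Extended
   (50–500 Hz) — then peak-normalize and cut fixed-length segments.
2. **Extract five acoustic features** per mode (15 per recording): energy,
   band power, zero-crossing rate, spectral centroid, and an MFCC summary.
3. **Classify** with a from-scratch multi-layer perceptron (15–30–20–1,
   tansig hidden layers, linear output), trained by full-batch
   backpropagation on the encoding healthy = 1 / unhealthy = 2 with decision
   threshold 1.5.
4. **Evaluate** on a stratified 70/15/15 train/validation/test split with
   confusion-matrix metrics (unhealthy is the positive class).

Because clinical recordings cannot ship with a package, a seeded synthetic
respiratory-sound simulator stands in for the corpus; every stage is testable
end to end without protected data.

## Preprocessing

**Filter realization.** Only band edges are specified by the stethoscope
modes, so the filters are order-4 Butterworth bandpass prototypes (order-8
transfer functions) applied forward–backward. Zero-phase filtering matters
here: crackles are 5–20 ms transients, and group delay would smear them
across segment boundaries. The signal mean is removed before filtering
(exact DC rejection) and the input is reflection-padded so startup
transients decay outside the recording. At the canonical 4000 Hz rate the
realized response is within ±1 dB of unity at each band center and more
than 20 dB down one octave outside either edge — the test suite checks the
realized gain of pure tones against the designed frequency response.

**Sample rate.** Recordings are resampled to 4000 Hz on load. Lung-sound
energy of interest lies below 2000 Hz, so this keeps every mode band below
Nyquist with margin while making the MFCC frame sizes small.

**Normalization** is peak normalization (max |sample| = 1), not z-scoring:
it removes recording-gain differences while keeping the mean-square energy
feature bounded by 1.

**Segmentation** uses 2.5 s frames with 50% overlap (hop 1.25 s) as a proxy
for one complete respiratory cycle (2–5 s in resting adults). A recording
shorter than one frame yields a single whole-recording segment. Both values
are arguments throughout.

## The 15 features

For each mode the recording is filtered, normalized, segmented, the five
features are computed per segment, and segments are averaged (the arithmetic
mean is the aggregation; features are defined per frame but reported per
recording, so an aggregator is unavoidable — the mean is the simplest
unbiased choice, at the cost of diluting rare, short events).

- **Energy**: `(1/N) Σ x²` — mean-square amplitude.
- **Band power**: mean Welch PSD over the bins inside the mode's band
  (Hann window of 1024 samples, 50% overlap, one-sided density). For white
  noise this estimates variance/Nyquist; the test suite checks the
  Parseval-style agreement between integrated PSD and energy.
- **Zero-crossing rate**: fraction of adjacent sample pairs with strictly
  opposite signs (a zero sample produces no crossing). Sensitive to
  high-frequency transients such as crackles.
- **Spectral centroid**: amplitude-weighted mean frequency of the one-sided
  magnitude spectrum of the whole segment (rectangular window); "brightness".
  Identically-zero segments return 0 Hz with a warning.
- **MFCC summary**: mel-frequency cepstral coefficients with a pinned
  definition — 25 ms periodic-Hann frames every 10 ms, FFT to the next power
  of two, power spectrum, 26 triangular HTK-mel filters spanning 0 to
  Nyquist, log with floor 1e-10, orthonormal DCT-II keeping c1..c13 (c0, a
  pure energy term, is excluded). The frame × coefficient matrix is reduced
  to one scalar by its grand mean. The reduction is an explicit choice
  (`reduce` argument): treating "MFCC" as a single feature requires one, and
  the grand mean keeps every coefficient's contribution while staying
  comparable across segment counts. The implementation is checked against an
  independent reference implementation of the same definition to 1e-4.

Feature vectors are assembled in a fixed canonical order (bell, diaphragm,
extended × energy, power, zcr, centroid, mfcc) and written to CSV with
17 significant digits, so matrices round-trip exactly for practical purposes.

## The classifier

The network is deliberately minimal — the four defining operations are
forward propagation `a^l = σ(W^l a^{l−1} + b^l)`, mean-squared-error loss,
the backpropagated error `δ^l = (W^{l+1})ᵀ δ^{l+1} ⊙ σ′(z^l)` with
`σ′ = 1 − tanh²` for tansig layers, and the plain gradient-descent update
`W^l ← W^l − η ∂L/∂W^l`. No momentum, minibatching or adaptive step sizes.
Analytic gradients are verified against central finite differences to a
relative error below 1e-5.

Choices worth recording:

- **Standardization.** Raw features span orders of magnitude (PSD levels of
  1e-5 next to centroids of several hundred Hz); tansig saturates without
  z-scoring. Statistics are fitted on the training split only and stored in
  the model checkpoint, so inference is self-contained.
- **Targets and threshold.** Labels are literally 1.0 and 2.0 under squared
  error — regression-style, as simple as a classifier gets. Scores at or
  above 1.5 are unhealthy; the tie at exactly 1.5 resolves to unhealthy,
  favoring sensitivity in a screening setting.
- **Initialization.** Uniform ±1/√fan_in weights, zero biases, reproducible
  per seed.
- **Training schedule.** η = 0.01, at most 10000 full-batch epochs, early
  stopping when validation MSE has not improved for 1000 epochs (the
  best-validation snapshot is returned). The generous patience is
  deliberate: at this learning rate the validation curve crosses long
  interim plateaus, and a short patience reliably halts while the network
  is still underfit (training MSE an order of magnitude above its
  attainable level). Divergence (non-finite loss) raises an error that
  suggests a smaller learning rate.
- **Architecture search.** `architecture_search()` trains each candidate
  hidden-layer layout with the same seed and configuration and reports
  validation accuracy, validation MSE and parameter count, selecting the
  accuracy argmax with ties broken toward fewer parameters; a diverging
  candidate becomes a failed row rather than aborting the search.

## Evaluation

`split_dataset()` assigns `round(n·0.15)` rows to validation and test and
the remainder to training, stratified by label (membership is invariant to
row order for a fixed seed: rows are keyed by sorted id before the seeded
shuffle). For 112 recordings this gives 78/17/17. Metrics are percentages:
accuracy, sensitivity, specificity, false-negative and false-positive rate,
with unhealthy as the positive class; undefined ratios (zero denominators)
are `NA` with a warning rather than fabricated zeros.

## The synthetic corpus

`generate_corpus()` emulates a 112-subject electronic-stethoscope corpus
(35 healthy, 77 patients). Its signal model, with the acoustic reasoning
behind each default:

- **Healthy (vesicular) breathing**: Gaussian noise bandpassed to
  60–400 Hz — normal breath sounds are low-pass with little energy above
  ~400 Hz — amplitude-modulated by a respiratory envelope (inspiration bump
  of amplitude 1 over 40% of the cycle, expiration bump of 0.35 over 35%:
  vesicular sounds are predominantly inspiratory), respiratory rate drawn
  from 12–20 breaths/min, duration from 5–30 s.
- **Wheezes** (airway narrowing): tones with mild vibrato and a weak second
  harmonic, gated to expiratory phases, ≥ 80 ms, frequencies 150–800 Hz,
  drawn per cycle with probability 0.9. Amplitude is expressed relative to
  the recording's overall breath RMS (ratio drawn 0.8–1.6): a wheezing
  expiration in diagnosed obstructive disease is loud — on the order of the
  inspiratory breath sound, not of the quiet vesicular expiration beneath it.
- **Crackles** (airway opening/fluid): 5–20 ms damped pops whose ringing
  frequency sweeps downward from 200–800 Hz — crackles are broadband, and
  the downward sweep guarantees energy inside the ≤ 500 Hz stethoscope
  bands. They arrive in inspiratory showers (10–30 per cycle) at 3–6× the
  local breath RMS (Gaussian breath noise itself peaks near 3× RMS, so
  anything quieter would be inaudible).
- **Breath character**: crackle-dominant recordings draw *bronchial*
  breathing (expiration as loud as inspiration, noise band extended ×1.5)
  with probability 0.7 (mixed profiles: 0.3) — consolidation in pneumonia
  and fibrosis transmits louder, higher-frequency breath sounds, and
  modeling the transients alone would under-represent those diseases.
- **Unhealthy profile mixture**: wheeze-dominant / crackle-dominant / mixed
  at 0.55 / 0.25 / 0.20, approximating the condition counts of the emulated
  cohort (asthma + COPD + bronchitis ≈ 57% obstructive; heart failure,
  fibrosis, pneumonia, effusion present with crackles).
- **Nuisance realism**: optional heart sounds (S1/S2 thuds at 40/55 Hz with
  smooth onsets — abrupt attacks would fake crackles — included with
  probability 0.3 in either class) and additive sensor noise at 25 dB SNR.
- If the per-cycle draws yield no adventitious event at all, one event of an
  enabled type is forced, so an "unhealthy" label is never vacuous. Partial
  trailing cycles receive events like any other cycle (events past the end
  are clipped).

All randomness descends from one master seed (per-recording seeds are drawn
from it and recorded in the manifest), so a corpus is a pure function of its
seed.

**What the simulator does not capture.** Real recordings carry ambient
noise, variable stethoscope placement and coupling, subject-specific
spectral shaping, disease-specific acoustics beyond generic
wheeze/crackle/bronchial patterns, and label noise. Passing the end-to-end
tests therefore demonstrates that the pipeline recovers the injected class
structure — that features carry the signal and the network can learn it —
not that the same accuracy would transfer to clinical data. The simulated
classes also retain genuinely ambiguous presentations (sparse low-pitched
events, faint crackles without bronchial breathing); note that on a
17-recording test split each recording is worth about 6 percentage points
of accuracy, so which ambiguous recordings a split seed assigns to the test
set materially moves the headline number.

## Numerical and degenerate-input policy

- Zero-length audio, non-finite samples, out-of-range WAV amplitudes and
  nonsensical configurations raise validation errors; degenerate but
  well-defined inputs (all-zero recording in `peak_normalize()` or
  `spectral_centroid()`) return the documented value with a warning.
- PCM16 scaling is symmetric: ±1 maps to ±32767 on write and read, −32768
  clamps to −1, so round trips stay within half an LSB.
- Welch PSD shrinks its window to the signal when shorter than 1024
  samples; band power raises an error when no PSD bin falls in the band.
- Ties at the decision threshold go to unhealthy; ties in architecture
  search go to fewer parameters.
- The experiment's sub-seeds derive from the master seed as corpus = seed,
  split = seed + 1, weight initialization = seed + 2.

## Problem sizes in the test suite

The unit and property tests run on seconds-long signals and small corpora
(6–26 recordings); the end-to-end acceptance experiment uses the full
default conditions (112 recordings, 15 features, 15–30–20–1 network), and
the effect-size monotonicity property uses 26-recording corpora at three
wheeze amplitudes × three seeds. These sizes are the package's chosen
trade-off between statistical resolution and suite runtime.

## Worked example

```{r example}
library(auscultate)

res <- run_experiment(experiment_config(seed = 42), quiet = FALSE)
res$report$splits$test$metrics

# single recordings
p <- synth_params(duration_s = 12, seed = 5,
                  wheeze = list(prob = 1, freq_hz = c(400, 400)))
rec <- synth_unhealthy(p)
extract_features(rec)
```

## Limitations

- Binary labels only; no per-disease classification and no event-level
  detection (the simulator's ground-truth event lists exist precisely so
  such extensions can be scored later).
- Fixed-length segmentation; no respiratory-cycle detection.
- The single-scalar MFCC reduction discards the coefficient profile's
  shape; it is kept because the feature set is fixed at 15, but the full
  matrix is available via `mfcc_matrix()`.
- Plain gradient descent is slow; it is retained because the update rule
  itself is part of what this package demonstrates.
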
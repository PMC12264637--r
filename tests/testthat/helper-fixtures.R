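# Shared fixtures and small oracles for the test suite. Everything is
# generated in code; nothing is read from disk.

make_tone <- function(freq, dur = 1, rate = 4000, amp = 0.5, id = NULL) {
  t <- seq(0, dur - 1 / rate, by = 1 / rate)
  recording(amp * sin(2 * pi * freq * t), rate,
            id = if (is.null(id)) paste0("tone", freq) else id)
}

rms <- function(x) sqrt(mean(x^2))

# frequency of the largest FFT magnitude (one-sided)
dominant_freq <- function(x, rate) {
  half <- length(x) %/% 2 + 1
  mag <- Mod(stats::fft(x))[seq_len(half)]
  mag[1] <- 0  # ignore DC
  (which.max(mag) - 1) * rate / length(x)
}

# squared magnitude response (forward-backward application) of the designed
# Butterworth bandpass at given frequencies — the filter-design oracle
filtfilt_gain <- function(mode, freqs, rate = 4000, order = 4) {
  bf <- signal::butter(order, c(mode$low_hz, mode$high_hz) * 2 / rate,
                       type = "pass")
  h <- signal::freqz(bf$b, bf$a, Fs = rate, n = 2^14)
  idx <- vapply(freqs, function(f) which.min(abs(h$f - f)), integer(1))
  Mod(h$h[idx])^2
}

# memoized full-scale seed-42 experiment shared by acceptance checks
.acc_env <- new.env(parent = emptyenv())
acceptance_experiment <- function() {
  if (is.null(.acc_env$res)) {
    .acc_env$res <- run_experiment(experiment_config(seed = 42))
  }
  .acc_env$res
}
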
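## Acoustic features: for each stethoscope mode the pipeline computes five
## scalars per segment -- mean-square energy, mean in-band PSD, zero-crossing
## rate, spectral centroid and an MFCC summary -- then averages over segments,
## giving the 15-element feature vector per recording (5 features x 3 modes).

#' Mean-square signal energy
#'
#' `(1/N) * sum(x_n^2)`: the sum of squared sample values normalized by the
#' signal length. Zero if and only if the signal is identically zero.
#'
#' @param x A `segment`, `recording` or numeric vector.
#' @return Nonnegative scalar.
#' @export
signal_energy <- function(x) {
  s <- .samples_of(x)
  mean(s^2)
}

#' Welch power spectral density
#'
#' Averaged modified periodogram: Hann-windowed segments of `nfft` samples at
#' 50% overlap, one-sided density scaling (the integral of the PSD over
#' `[0, Nyquist]` estimates the signal's mean square). Segments shorter than
#' `nfft` are handled by shrinking the window to the signal length.
#'
#' @param x A `segment`, `recording` or numeric vector.
#' @param rate Sample rate in Hz (taken from `x` when it carries one).
#' @param nfft Window/FFT length in samples (default 1024).
#' @param overlap Fractional overlap between windows (default 0.5).
#' @return A list with `freq` (Hz) and `psd` (power per Hz), class
#'   `power_spectrum`.
#' @export
welch_psd <- function(x, rate = NULL, nfft = 1024, overlap = 0.5) {
  s <- .samples_of(x)
  fs <- .rate_of(x, rate)
  nfft <- min(as.integer(nfft), length(s))
  if (nfft < 2L) stop("signal too short for a PSD window", call. = FALSE)
  hop <- max(1L, as.integer(round(nfft * (1 - overlap))))
  starts <- seq(1L, length(s) - nfft + 1L, by = hop)
  n <- 0:(nfft - 1L)
  w <- 0.5 - 0.5 * cos(2 * pi * n / nfft)          # periodic Hann
  scale <- fs * sum(w^2)
  frames <- vapply(starts, function(i) s[i:(i + nfft - 1L)] * w,
                   numeric(nfft))
  spec <- Mod(stats::mvfft(frames))^2 / scale
  half <- nfft %/% 2L + 1L
  p <- rowMeans(spec[seq_len(half), , drop = FALSE])
  # fold negative frequencies into the one-sided density
  interior <- 2L:(half - 1L + nfft %% 2L)
  p[interior] <- 2 * p[interior]
  structure(list(freq = (seq_len(half) - 1L) * fs / nfft, psd = p,
                 kind = "psd"),
            class = "power_spectrum")
}

#' Average band power
#'
#' Mean power spectral density over the frequency bins lying inside a
#' stethoscope mode's emphasis band: `(1/K) * sum(P(f_k))` over the `K`
#' in-band bins of the Welch PSD.
#'
#' @param x A `segment`, `recording` or numeric vector.
#' @param mode A [filter_mode()] giving the band `[low_hz, high_hz]`.
#' @param rate Sample rate in Hz if `x` is a bare vector.
#' @param nfft Welch window length (default 1024).
#' @return Nonnegative scalar (power per Hz averaged over the band).
#' @export
band_power <- function(x, mode, rate = NULL, nfft = 1024) {
  stopifnot(inherits(mode, "filter_mode"))
  ps <- welch_psd(x, rate = rate, nfft = nfft)
  inband <- ps$freq >= mode$low_hz & ps$freq <= mode$high_hz
  if (!any(inband)) {
    stop("no PSD bin falls inside ", mode$low_hz, "-", mode$high_hz,
         " Hz; frequency resolution too coarse for the band", call. = FALSE)
  }
  mean(ps$psd[inband])
}

#' Zero-crossing rate
#'
#' Fraction of adjacent sample pairs with strictly opposite signs:
#' `(1/(N-1)) * sum(x_n * x_{n+1} < 0)`. A zero-valued sample produces no
#' crossing under the strict inequality.
#'
#' @param x A `segment`, `recording` or numeric vector of length >= 2.
#' @return Scalar in `[0, 1]`.
#' @export
zero_crossing_rate <- function(x) {
  s <- .samples_of(x)
  n <- length(s)
  if (n < 2L) stop("zero-crossing rate needs at least 2 samples", call. = FALSE)
  sum(s[-n] * s[-1L] < 0) / (n - 1L)
}

#' Spectral centroid
#'
#' Amplitude-weighted mean frequency `sum(f_k |X_k|) / sum(|X_k|)` over the
#' one-sided magnitude spectrum of the whole segment (rectangular window).
#' An identically-zero segment returns 0 Hz with a warning (the denominator
#' would vanish).
#'
#' @param x A `segment`, `recording` or numeric vector.
#' @param rate Sample rate in Hz if `x` is a bare vector.
#' @return Centroid frequency in Hz, in `[0, Nyquist]`.
#' @export
spectral_centroid <- function(x, rate = NULL) {
  s <- .samples_of(x)
  fs <- .rate_of(x, rate)
  if (all(s == 0)) {
    warning("identically-zero segment: spectral centroid reported as 0 Hz",
            call. = FALSE)
    return(0)
  }
  n <- length(s)
  half <- n %/% 2L + 1L
  mag <- Mod(stats::fft(s))[seq_len(half)]
  freq <- (seq_len(half) - 1L) * fs / n
  sum(freq * mag) / sum(mag)
}

#' MFCC configuration
#'
#' Parameters of the mel-frequency cepstral pipeline:
#' short-time Fourier transform with a periodic Hann window of `win_s`
#' seconds every `hop_s` seconds, an `n_mels`-filter triangular mel filterbank
#' (HTK mel scale, `2595*log10(1 + f/700)`) on the power spectrum, a log with
#' floor `log_floor`, and an orthonormal DCT-II keeping coefficients
#' `c1..c{n_coeffs}` (the energy-like `c0` is excluded).
#'
#' @param n_mels Number of mel filters (default 26).
#' @param n_coeffs Number of kept cepstral coefficients (default 13;
#'   must be < `n_mels`).
#' @param win_s STFT window in seconds (default 0.025).
#' @param hop_s STFT hop in seconds (default 0.010).
#' @param log_floor Floor applied before the log (default 1e-10).
#' @return An `mfcc_config` object.
#' @export
mfcc_config <- function(n_mels = 26, n_coeffs = 13, win_s = 0.025,
                        hop_s = 0.010, log_floor = 1e-10) {
  if (n_coeffs >= n_mels) stop("need n_coeffs < n_mels", call. = FALSE)
  if (!(win_s >= hop_s && hop_s > 0)) {
    stop("need win_s >= hop_s > 0", call. = FALSE)
  }
  if (log_floor <= 0) stop("log_floor must be > 0", call. = FALSE)
  structure(list(n_mels = as.integer(n_mels), n_coeffs = as.integer(n_coeffs),
                 win_s = win_s, hop_s = hop_s, log_floor = log_floor),
            class = "mfcc_config")
}

.hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
.mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# Triangular mel filterbank (n_mels x n_bins) on FFT bin frequencies,
# HTK-style (unit peak, no area normalization).
.mel_filterbank <- function(n_mels, nfft, fs) {
  half <- nfft %/% 2L + 1L
  bin_freq <- (seq_len(half) - 1L) * fs / nfft
  edges <- .mel_to_hz(seq(.hz_to_mel(0), .hz_to_mel(fs / 2),
                          length.out = n_mels + 2L))
  fb <- matrix(0, n_mels, half)
  for (m in seq_len(n_mels)) {
    lo <- edges[m]; ct <- edges[m + 1L]; hi <- edges[m + 2L]
    up <- (bin_freq - lo) / (ct - lo)
    down <- (hi - bin_freq) / (hi - ct)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  fb
}

# Orthonormal DCT-II matrix (n_keep x n_mels), rows k = 1..n_keep (c0 excluded).
.dct_matrix <- function(n_keep, n_mels) {
  k <- seq_len(n_keep)
  m <- seq_len(n_mels) - 0.5
  sqrt(2 / n_mels) * cos(pi * outer(k, m) / n_mels)
}

#' MFCC matrix of a segment
#'
#' Frames the segment, takes the power spectrum of each Hann-windowed frame
#' (FFT length the next power of two above the window), applies the mel
#' filterbank and floored log, and returns the orthonormal DCT-II
#' coefficients `c1..c{n_coeffs}` per frame.
#'
#' @inheritParams spectral_centroid
#' @param config An [mfcc_config()].
#' @return Numeric matrix, frames x `n_coeffs`.
#' @export
mfcc_matrix <- function(x, config = mfcc_config(), rate = NULL) {
  stopifnot(inherits(config, "mfcc_config"))
  s <- .samples_of(x)
  fs <- .rate_of(x, rate)
  win <- as.integer(round(config$win_s * fs))
  hop <- as.integer(round(config$hop_s * fs))
  if (length(s) < win) {
    stop("segment (", length(s), " samples) is shorter than the MFCC window (",
         win, " samples)", call. = FALSE)
  }
  nfft <- 2L^ceiling(log2(win))
  starts <- seq(1L, length(s) - win + 1L, by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(win - 1L)) / win)
  frames <- vapply(starts, function(i) {
    c(s[i:(i + win - 1L)] * w, numeric(nfft - win))
  }, numeric(nfft))
  half <- nfft %/% 2L + 1L
  pow <- Mod(stats::mvfft(frames))[seq_len(half), , drop = FALSE]^2
  fb <- .mel_filterbank(config$n_mels, nfft, fs)
  logmel <- log(pmax(fb %*% pow, config$log_floor))
  t(.dct_matrix(config$n_coeffs, config$n_mels) %*% logmel)
}

#' MFCC summary scalar
#'
#' The single MFCC feature used in the 15-element vector: the grand mean of
#' the [mfcc_matrix()] over frames and coefficients. The reduction is
#' deliberately isolated behind `reduce` so alternatives (e.g. the first
#' coefficient only) can be swapped in.
#'
#' @inheritParams mfcc_matrix
#' @param reduce Function collapsing the coefficient matrix to one scalar.
#' @return A single finite scalar.
#' @export
mfcc_scalar <- function(x, config = mfcc_config(), rate = NULL,
                        reduce = mean) {
  reduce(mfcc_matrix(x, config, rate))
}

#' Extract the 15-element feature vector of a recording
#'
#' For each stethoscope mode: bandpass filter, peak-normalize, segment, then
#' compute the five features per segment and average over segments. The 15
#' scalars are returned in canonical order: for each of bell, diaphragm,
#' extended in turn -- energy, power, zcr, centroid, mfcc.
#'
#' @param recording A raw (unfiltered) [recording()] at the canonical rate.
#' @param modes Named list of [filter_mode()]s (default [filter_modes()]).
#' @param frame_s,hop_s Segmentation parameters (defaults 2.5 s / 1.25 s).
#' @param config An [mfcc_config()].
#' @return Named numeric vector of 15 features with attributes `id` and
#'   `label`, class `feature_vector`.
#' @export
extract_features <- function(recording, modes = filter_modes(),
                             frame_s = 2.5, hop_s = 1.25,
                             config = mfcc_config()) {
  stopifnot(inherits(recording, "recording"))
  out <- numeric(0)
  for (mode in modes) {
    vals <- tryCatch({
      filtered <- peak_normalize(bandpass_filter(recording, mode))
      segs <- segment_recording(filtered, frame_s = frame_s, hop_s = hop_s)
      per_seg <- vapply(segs, function(sg) {
        c(energy = signal_energy(sg),
          power = band_power(sg, mode),
          zcr = zero_crossing_rate(sg),
          centroid = spectral_centroid(sg),
          mfcc = mfcc_scalar(sg, config))
      }, numeric(5))
      rowMeans(per_seg)
    }, error = function(e) {
      stop("feature extraction failed for recording '", recording$id,
           "', mode '", mode$name, "': ", conditionMessage(e), call. = FALSE)
    })
    names(vals) <- paste(mode$name, names(vals), sep = "_")
    out <- c(out, vals)
  }
  structure(out, id = recording$id, label = recording$label,
            class = c("feature_vector", "numeric"))
}

#' Canonical feature column names
#' @return Character vector of the 15 feature names in canonical order.
#' @export
feature_names <- function() {
  as.vector(t(outer(c("bell", "diaphragm", "extended"),
                    c("energy", "power", "zcr", "centroid", "mfcc"),
                    paste, sep = "_")))
}

#' Build the feature matrix for a set of recordings
#'
#' @param recordings List of [recording()]s with unique ids.
#' @inheritParams extract_features
#' @return A data.frame with columns `id`, `label` and the 15 feature columns,
#'   one row per recording in input order.
#' @export
build_feature_matrix <- function(recordings, modes = filter_modes(),
                                 frame_s = 2.5, hop_s = 1.25,
                                 config = mfcc_config()) {
  if (length(recordings) < 1L) stop("need at least one recording", call. = FALSE)
  ids <- vapply(recordings, function(r) r$id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate recording ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  rows <- lapply(recordings, function(r) {
    fv <- extract_features(r, modes = modes, frame_s = frame_s, hop_s = hop_s,
                           config = config)
    cbind(data.frame(id = attr(fv, "id"),
                     label = if (is.null(attr(fv, "label"))) NA_character_
                             else attr(fv, "label"),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(unclass(fv))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read a feature matrix as CSV
#'
#' Full-precision round trip (values written with 17 significant digits).
#'
#' @param features Data.frame as returned by [build_feature_matrix()].
#' @param path CSV path.
#' @return `read_feature_csv` returns the data.frame; `write_feature_csv`
#'   returns `path` invisibly.
#' @export
write_feature_csv <- function(features, path) {
  fmt <- features
  num <- vapply(fmt, is.numeric, logical(1))
  fmt[num] <- lapply(fmt[num], function(v) sprintf("%.17g", v))
  utils::write.csv(fmt, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  out
}
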
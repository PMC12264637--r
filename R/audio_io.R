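#' Construct a Recording
#'
#' A `recording` is the package's basic audio container: a mono sample vector
#' with its sample rate and light metadata. Amplitudes are dimensionless and
#' expected in `[-1, 1]` after loading from file.
#'
#' @param samples Numeric vector of mono samples; all values must be finite.
#' @param rate Sample rate in Hz (> 0).
#' @param id Opaque identifier string.
#' @param label Optional class label, `"healthy"` or `"unhealthy"`.
#' @param filter_mode Optional [filter_mode()] already applied to the samples.
#' @return An object of class `recording`.
#' @seealso [read_wav()], [write_wav()], [resample_recording()]
#' @export
recording <- function(samples, rate, id = "rec", label = NULL,
                      filter_mode = NULL) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) {
    stop("recording must contain at least one sample", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("recording samples must all be finite", call. = FALSE)
  }
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0) {
    stop("sample rate must be a single positive number", call. = FALSE)
  }
  if (!is.null(label)) {
    label <- match.arg(label, c("healthy", "unhealthy"))
  }
  structure(
    list(samples = samples, rate = as.numeric(rate), id = as.character(id),
         label = label, filter_mode = filter_mode),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  dur <- length(x$samples) / x$rate
  cat(sprintf("<recording '%s'> %d samples @ %g Hz (%.2f s)", x$id,
              length(x$samples), x$rate, dur))
  if (!is.null(x$label)) cat(", label:", x$label)
  if (!is.null(x$filter_mode)) cat(", mode:", x$filter_mode$name)
  cat("\n")
  invisible(x)
}

#' Duration of a recording in seconds
#' @param recording A [recording()].
#' @return Duration in seconds.
#' @export
duration <- function(recording) {
  stopifnot(inherits(recording, "recording"))
  length(recording$samples) / recording$rate
}

# Canonical internal rate: covers the 20-2000 Hz stethoscope range with
# Nyquist margin.
#' Default internal sample rate (Hz)
#' @return 4000.
#' @export
canonical_rate <- function() 4000

## ---- WAV (RIFF) reading and writing --------------------------------------
## Minimal RIFF parser: PCM (format 1) at 8/16/24/32 bit and IEEE float
## (format 3) at 32/64 bit, plus WAVE_FORMAT_EXTENSIBLE wrappers. Multichannel
## audio is averaged to mono; integer PCM is rescaled so full scale maps to
## +-1 (16-bit: divide by 32767, -32768 clamped to -1).

#' Read a WAV file into a recording
#'
#' Accepts RIFF/WAVE files holding integer PCM (8, 16, 24 or 32 bit) or IEEE
#' float (32 or 64 bit) audio. Multichannel audio is averaged to mono (the
#' stethoscope source is mono; this is robustness only). Integer PCM is
#' divided by its positive full scale so that e.g. a 16-bit value of +32767
#' loads as exactly +1; -32768 is clamped to -1.
#'
#' @param path Path to a WAV file.
#' @param id Identifier for the returned recording; defaults to the file name.
#' @param label Optional class label passed through to the recording.
#' @return A [recording()].
#' @export
read_wav <- function(path, id = NULL, label = NULL) {
  if (!file.exists(path)) {
    stop("cannot read WAV file: '", path, "' does not exist", call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  fail <- function(why) {
    stop("cannot read WAV file '", path, "': ", why, call. = FALSE)
  }
  hdr <- readChar(con, 4, useBytes = TRUE)
  if (!identical(hdr, "RIFF")) fail("not a RIFF file")
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE")) {
    fail("not a WAVE file")
  }

  fmt <- NULL
  raw_data <- NULL
  repeat {
    tag <- readChar(con, 4, useBytes = TRUE)
    if (length(tag) == 0L || nchar(tag) < 4L) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (length(sz) == 0L) break
    if (identical(tag, "fmt ")) {
      body <- readBin(con, "raw", sz)
      if (length(body) < 16L) fail("truncated fmt chunk")
      u16 <- function(i) {
        sum(as.integer(body[i:(i + 1L)]) * c(1, 256))
      }
      u32 <- function(i) {
        sum(as.numeric(body[i:(i + 3L)]) * c(1, 256, 65536, 16777216))
      }
      fmt <- list(code = u16(1L), channels = u16(3L), rate = u32(5L),
                  bits = u16(15L))
      if (fmt$code == 65534L && length(body) >= 26L) {
        # WAVE_FORMAT_EXTENSIBLE: true format is the first two bytes of the
        # 16-byte subformat GUID at offset 24.
        fmt$code <- u16(25L)
      }
    } else if (identical(tag, "data")) {
      raw_data <- readBin(con, "raw", sz)
      break
    } else {
      invisible(readBin(con, "raw", sz + (sz %% 2L)))
    }
  }
  if (is.null(fmt)) fail("no fmt chunk found")
  if (is.null(raw_data)) fail("no data chunk found")
  if (!fmt$code %in% c(1L, 3L)) {
    fail(sprintf("unsupported format code %d (only PCM and IEEE float)",
                 fmt$code))
  }
  bytes_per <- fmt$bits %/% 8L
  n_total <- length(raw_data) %/% bytes_per
  if (n_total < 1L) fail("zero-length audio data")

  x <- if (fmt$code == 3L) {
    if (!fmt$bits %in% c(32L, 64L)) fail("float WAV must be 32 or 64 bit")
    readBin(raw_data, "double", n_total, size = bytes_per, endian = "little")
  } else if (fmt$bits == 8L) {
    # 8-bit PCM is unsigned with midpoint 128
    (as.numeric(readBin(raw_data, "integer", n_total, size = 1L,
                        signed = FALSE)) - 128) / 127
  } else if (fmt$bits %in% c(16L, 32L)) {
    full <- 2^(fmt$bits - 1) - 1
    readBin(raw_data, "integer", n_total, size = bytes_per,
            endian = "little") / full
  } else if (fmt$bits == 24L) {
    m <- matrix(as.integer(raw_data[seq_len(n_total * 3L)]), nrow = 3L)
    v <- m[1L, ] + 256 * m[2L, ] + 65536 * m[3L, ]
    v <- ifelse(v >= 8388608, v - 16777216, v)
    v / 8388607
  } else {
    fail(sprintf("unsupported PCM bit depth %d", fmt$bits))
  }
  x <- pmax(x, -1)

  if (fmt$channels > 1L) {
    n_frames <- length(x) %/% fmt$channels
    x <- colMeans(matrix(x[seq_len(n_frames * fmt$channels)],
                         nrow = fmt$channels))
  }
  if (length(x) < 1L) fail("zero-length audio data")
  recording(x, fmt$rate, id = if (is.null(id)) basename(path) else id,
            label = label)
}

#' Write a recording to a WAV file
#'
#' @param recording A [recording()] with samples in `[-1, 1]`; out-of-range
#'   samples are a validation error (no silent clipping).
#' @param path Output path; the directory must exist.
#' @param bits Either 16 (integer PCM, default) or 32 (IEEE float).
#' @return Invisibly, `path`.
#' @export
write_wav <- function(recording, path, bits = 16) {
  stopifnot(inherits(recording, "recording"))
  if (!bits %in% c(16, 32)) {
    stop("bits must be 16 (PCM) or 32 (IEEE float)", call. = FALSE)
  }
  x <- recording$samples
  if (max(abs(x)) > 1) {
    stop("samples exceed [-1, 1]; rescale (e.g. peak_normalize) before writing",
         call. = FALSE)
  }
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    stop("cannot write WAV file: directory '", dir, "' does not exist",
         call. = FALSE)
  }
  rate <- as.integer(round(recording$rate))
  n <- length(x)
  bytes_per <- bits %/% 8L
  data_size <- n * bytes_per

  con <- file(path, "wb")
  on.exit(close(con))
  w32 <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  w16 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")
  writeChar("RIFF", con, eos = NULL)
  w32(36L + data_size)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  w32(16L)
  w16(if (bits == 16) 1L else 3L)       # PCM or IEEE float
  w16(1L)                                # mono
  w32(rate)
  w32(rate * bytes_per)                  # byte rate
  w16(bytes_per)                         # block align
  w16(bits)
  writeChar("data", con, eos = NULL)
  w32(data_size)
  if (bits == 16) {
    writeBin(as.integer(round(x * 32767)), con, size = 2, endian = "little")
  } else {
    writeBin(as.numeric(x), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Resample a recording to a new rate
#'
#' Polyphase resampling (via [signal::resample()]) at the rational ratio
#' `target_rate / rate`. Duration is conserved to within one sample period and
#' tones below the output Nyquist are preserved.
#'
#' @param recording A [recording()].
#' @param target_rate Target sample rate in Hz (> 0).
#' @return A [recording()] at `target_rate`.
#' @export
resample_recording <- function(recording, target_rate) {
  stopifnot(inherits(recording, "recording"))
  if (!is.numeric(target_rate) || length(target_rate) != 1L ||
      !is.finite(target_rate) || target_rate <= 0) {
    stop("target_rate must be a single positive number", call. = FALSE)
  }
  if (isTRUE(all.equal(target_rate, recording$rate))) {
    return(recording)
  }
  frac <- .as_fraction(target_rate / recording$rate)
  y <- signal::resample(recording$samples, frac[1L], frac[2L])
  n_expect <- round(length(recording$samples) * target_rate / recording$rate)
  y <- y[seq_len(min(length(y), n_expect))]
  recording(y, target_rate, id = recording$id, label = recording$label,
            filter_mode = recording$filter_mode)
}

# Rational approximation p/q of a positive ratio (continued fractions).
.as_fraction <- function(r, max_den = 10000L) {
  p0 <- 0; q0 <- 1; p1 <- 1; q1 <- 0
  x <- r
  repeat {
    a <- floor(x)
    p2 <- a * p1 + p0
    q2 <- a * q1 + q0
    if (q2 > max_den) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(p1 / q1 - r) < 1e-12) break
    if (x - a < 1e-12) break
    x <- 1 / (x - a)
  }
  c(as.integer(p1), as.integer(q1))
}
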
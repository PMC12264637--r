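## Synthetic auscultation recordings. Healthy (vesicular) lung sounds are
## modeled as low-pass breath noise (most energy below ~400 Hz) amplitude-
## modulated by an inspiration/expiration envelope with the quieter
## expiration typical of vesicular sounds. Unhealthy recordings add
## adventitious events on top of the same base: wheezes (sustained tonal
## sounds >= 80 ms, gated to the expiratory phase) and/or crackles (<= 20 ms
## exponentially damped high-frequency transients). Event amplitudes are
## scaled to the LOCAL breath-sound amplitude they ride on — an amplitude
## ratio of 1 means "as loud as the breath sound underneath", which is what
## makes real adventitious sounds audible. Optional low-frequency heart-sound
## contamination and additive sensor noise complete the model. Everything is
## deterministic per seed.

#' Parameters of the synthetic recording generator
#'
#' Defaults emulate the kind of corpus an electronic stethoscope study
#' collects: 5-30 s recordings containing at least one full respiratory
#' cycle, vesicular breath noise concentrated in a 60-400 Hz band, wheezes of
#' at least 80 ms in the 150-800 Hz range, crackles of 5-20 ms with dominant
#' oscillation frequencies of 200-800 Hz (coarse crackles near the low end,
#' fine crackles near the high end), heart sounds in 20-150 Hz, and a 25 dB
#' signal-to-sensor-noise ratio.
#'
#' @param duration_s Recording length in seconds, within `[5, 30]`.
#' @param breath_rate_bpm Respiratory rate, breaths per minute.
#' @param noise_band Length-2 Hz band of the breath noise.
#' @param wheeze List: `prob` (per respiratory cycle), `freq_hz` (length-2
#'   range), `duration_s` (`NULL` = the whole expiratory phase; otherwise
#'   >= 0.08 s), `amp_ratio` (amplitude relative to the recording's overall
#'   breath-sound RMS; 1 = a wheezing expiration about as loud as the
#'   inspiratory breath sound, as in obstructive disease).
#' @param crackle List: `count` (expected per cycle), `freq_hz` (length-2
#'   range of the damped oscillation), `duration_s` (0.005-0.02 s),
#'   `amp_ratio` (relative to the local breath-sound RMS around the crackle).
#' @param heart List: `include` flag, `rate_bpm`, `band` (Hz, informative),
#'   `amp_ratio`.
#' @param bronchial Breath character flag. `FALSE` (default) gives normal
#'   vesicular breathing (quiet expiration, low-pass noise). `TRUE` gives
#'   bronchial breathing as heard over consolidated lung (pneumonia,
#'   fibrosis): an expiratory phase as loud as inspiration and breath-noise
#'   content extending higher in frequency.
#' @param snr_db Signal-to-sensor-noise ratio in dB.
#' @param rate Sample rate in Hz (default [canonical_rate()]).
#' @param seed Integer seed; generation is deterministic per seed.
#' @param id Identifier for the generated recording.
#' @return A validated `synth_params` list.
#' @export
synth_params <- function(duration_s = 15, breath_rate_bpm = 16,
                         noise_band = c(60, 400),
                         wheeze = list(prob = 0.9, freq_hz = c(150, 800),
                                       duration_s = NULL, amp_ratio = 1.0),
                         crackle = list(count = 15, freq_hz = c(200, 800),
                                        duration_s = 0.012, amp_ratio = 4.0),
                         heart = list(include = FALSE, rate_bpm = 70,
                                      band = c(20, 150), amp_ratio = 0.5),
                         bronchial = FALSE,
                         snr_db = 25, rate = canonical_rate(), seed = 1,
                         id = "synth") {
  defaults <- formals(synth_params)
  wheeze <- utils::modifyList(eval(defaults$wheeze), wheeze)
  crackle <- utils::modifyList(eval(defaults$crackle), crackle)
  heart <- utils::modifyList(eval(defaults$heart), heart)
  if (duration_s < 5 || duration_s > 30) {
    stop("duration_s must lie in [5, 30] seconds", call. = FALSE)
  }
  if (breath_rate_bpm <= 0) stop("breath_rate_bpm must be > 0", call. = FALSE)
  if (duration_s < 60 / breath_rate_bpm) {
    stop("duration too short for one respiratory cycle at ",
         breath_rate_bpm, " bpm", call. = FALSE)
  }
  if (!is.null(wheeze$duration_s) && wheeze$duration_s < 0.08) {
    stop("wheeze duration must be >= 0.08 s", call. = FALSE)
  }
  if (crackle$duration_s > 0.02 || crackle$duration_s < 0.005) {
    stop("crackle duration must lie in [0.005, 0.02] s", call. = FALSE)
  }
  if (wheeze$amp_ratio < 0 || crackle$amp_ratio < 0 || heart$amp_ratio < 0) {
    stop("amplitude ratios must be >= 0", call. = FALSE)
  }
  structure(list(duration_s = duration_s, breath_rate_bpm = breath_rate_bpm,
                 noise_band = noise_band, wheeze = wheeze, crackle = crackle,
                 heart = heart, bronchial = isTRUE(bronchial),
                 snr_db = snr_db, rate = rate,
                 seed = as.integer(seed), id = as.character(id)),
            class = "synth_params")
}

# Respiratory-cycle amplitude envelope: inspiration bump (40% of the cycle,
# amplitude 1), pause, expiration bump (35%), pause; floor 0.08 so breath
# noise never vanishes entirely. Vesicular breathing has a quiet expiration
# (amplitude 0.35); bronchial breathing, heard over consolidated lung, has
# an expiration as loud as inspiration.
.breath_envelope <- function(n, rate, bpm, bronchial = FALSE) {
  t <- (seq_len(n) - 1L) / rate
  cycle <- 60 / bpm
  phase <- (t %% cycle) / cycle
  env <- rep(0.08, n)
  insp <- phase < 0.40
  env[insp] <- 0.08 + 0.92 * sin(pi * phase[insp] / 0.40)
  exp_amp <- if (bronchial) 0.87 else 0.27
  exp_ph <- phase >= 0.45 & phase < 0.80
  env[exp_ph] <- 0.08 + exp_amp * sin(pi * (phase[exp_ph] - 0.45) / 0.35)
  env
}

# Deterministic base signal shared by healthy and unhealthy generation:
# enveloped band-limited breath noise + optional heart sounds + sensor noise.
.synth_base <- function(params) {
  n <- round(params$duration_s * params$rate)
  band <- params$noise_band
  if (params$bronchial) {
    # consolidation transmits higher frequencies to the chest wall
    band[2] <- min(band[2] * 1.5, 0.45 * params$rate)
  }
  with_seed(params$seed, {
    noise <- stats::rnorm(n)
    bf <- signal::butter(4, band * 2 / params$rate, type = "pass")
    breath <- signal::filtfilt(bf, noise)
    breath <- breath / stats::sd(breath)
    env <- .breath_envelope(n, params$rate, params$breath_rate_bpm,
                            params$bronchial)
    x <- breath * env

    if (isTRUE(params$heart$include)) {
      beat <- 60 / params$heart$rate_bpm
      t_beat <- seq(0.05, params$duration_s - 0.4, by = beat)
      thump <- function(f0, dur, amp) {
        tt <- seq(0, dur, by = 1 / params$rate)
        # smooth onset and decay: heart sounds are low-frequency thuds, not
        # clicks — an abrupt attack would add spurious broadband content
        env <- sin(pi * tt / dur)^2 * exp(-2 * tt / dur)
        amp * env * sin(2 * pi * f0 * tt)
      }
      s1 <- thump(40, 0.12, 1.0)
      s2 <- thump(55, 0.09, 0.7)
      amp <- params$heart$amp_ratio * stats::sd(x)
      for (tb in t_beat) {
        i1 <- round(tb * params$rate) + 1L
        i2 <- round((tb + 0.30) * params$rate) + 1L
        k1 <- seq_along(s1); k2 <- seq_along(s2)
        ok1 <- (i1 + k1 - 1L) <= n
        ok2 <- (i2 + k2 - 1L) <= n
        x[i1 + k1[ok1] - 1L] <- x[i1 + k1[ok1] - 1L] + amp * s1[ok1]
        x[i2 + k2[ok2] - 1L] <- x[i2 + k2[ok2] - 1L] + amp * s2[ok2]
      }
    }
    sensor <- stats::rnorm(n) * stats::sd(x) * 10^(-params$snr_db / 20)
    x + sensor
  })
}

.finalize_synth <- function(x, params, label, events) {
  # keep pre-normalization headroom: peak at 0.9 so max |sample| <= 1 holds
  x <- 0.9 * x / max(abs(x))
  rec <- recording(x, params$rate, id = params$id, label = label)
  attr(rec, "events") <- events
  rec
}

.empty_events <- function() {
  data.frame(type = character(0), time_s = numeric(0), freq_hz = numeric(0),
             duration_s = numeric(0), amplitude = numeric(0),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic healthy recording
#'
#' Band-limited breath noise amplitude-modulated by the respiratory envelope,
#' optional heart sounds and sensor noise; no adventitious events.
#'
#' @param params A [synth_params()].
#' @return A [recording()] labeled `"healthy"`, with an empty `events`
#'   attribute.
#' @export
synth_healthy <- function(params = synth_params()) {
  stopifnot(inherits(params, "synth_params"))
  .finalize_synth(.synth_base(params), params, "healthy", .empty_events())
}

#' Generate a synthetic unhealthy recording
#'
#' The healthy base for the same seed, plus adventitious events: wheezes
#' (frequency-jittered tones gated to expiratory phases, Hann-enveloped)
#' drawn per cycle with probability `wheeze$prob`, and crackles (exponentially
#' damped sinusoids at random in-cycle offsets) with a Poisson-distributed
#' count per cycle of mean `crackle$count`. If the random draw yields no
#' event at all, one event of an enabled type is forced so the unhealthy
#' label is never vacuous. The ground-truth event list is attached as the
#' `events` attribute.
#'
#' @param params A [synth_params()]; at least one of `wheeze$prob > 0` or
#'   `crackle$count > 0` is required.
#' @return A [recording()] labeled `"unhealthy"` with an `events` attribute
#'   (data.frame: type, time_s, freq_hz, duration_s, amplitude).
#' @export
synth_unhealthy <- function(params = synth_params()) {
  stopifnot(inherits(params, "synth_params"))
  if (params$wheeze$prob <= 0 && params$crackle$count <= 0) {
    stop("unhealthy synthesis needs wheeze$prob > 0 or crackle$count > 0 ",
         "(otherwise the label would be wrong)", call. = FALSE)
  }
  base <- .synth_base(params)
  n <- length(base)
  fs <- params$rate
  base_rms <- stats::sd(base)
  # local breath-sound loudness: RMS of the base over a given index window
  local_rms <- function(idx) {
    idx <- idx[idx >= 1L & idx <= n]
    sqrt(mean(base[idx]^2))
  }
  cycle <- 60 / params$breath_rate_bpm
  # count partial trailing cycles too: their expirations carry events as
  # well (events falling past the end of the recording are clipped/skipped)
  n_cycles <- max(1L, ceiling(params$duration_s / cycle))
  events <- .empty_events()
  x <- base

  add_wheeze <- function(x, events, cycle_start) {
    f0 <- stats::runif(1, params$wheeze$freq_hz[1], params$wheeze$freq_hz[2])
    start <- cycle_start + 0.45 * cycle
    dur <- if (is.null(params$wheeze$duration_s)) 0.35 * cycle
           else params$wheeze$duration_s
    dur <- min(dur, params$duration_s - start)
    if (dur < 0.08) return(list(x = x, events = events))
    tt <- seq(0, dur - 1 / fs, by = 1 / fs)
    # mild vibrato so the tone is not a single FFT line, plus a weak second
    # harmonic (wheezes are rarely pure sinusoids)
    ph <- 2 * pi * f0 * tt + 0.8 * sin(2 * pi * 3 * tt)
    tone <- sin(ph) + 0.3 * sin(2 * ph)
    win <- 0.5 - 0.5 * cos(2 * pi * seq_along(tt) / length(tt))
    i0 <- round(start * fs) + 1L
    idx <- i0:(i0 + length(tt) - 1L)
    # a wheezing expiration is loud — on the order of the recording's overall
    # breath-sound level, not of the quiet vesicular expiration beneath it
    amp <- params$wheeze$amp_ratio * sqrt(2) * base_rms
    keep <- idx <= n
    x[idx[keep]] <- x[idx[keep]] + amp * (tone * win)[keep]
    events <- rbind(events, data.frame(type = "wheeze", time_s = start,
                                       freq_hz = f0, duration_s = dur,
                                       amplitude = amp))
    list(x = x, events = events)
  }

  add_crackle <- function(x, events, cycle_start) {
    f0 <- stats::runif(1, params$crackle$freq_hz[1], params$crackle$freq_hz[2])
    # crackles are predominantly (end-)inspiratory
    start <- cycle_start + stats::runif(1, 0.05, 0.50) * cycle
    dur <- params$crackle$duration_s
    if (start + dur >= params$duration_s) {
      return(list(x = x, events = events))
    }
    tt <- seq(0, dur, by = 1 / fs)
    tau <- dur / 4
    # crackles are broadband pops: the ringing frequency sweeps downward
    # (sharp initial deflection, coarser tail), so in-band energy survives
    # the stethoscope-mode filters wherever f0 is drawn
    f_inst <- f0 * (1 - 0.7 * tt / dur)
    phase <- 2 * pi * cumsum(f_inst) / fs
    pulse <- exp(-tt / tau) * sin(phase)
    i0 <- round(start * fs) + 1L
    # prominence relative to the breath sound in the surrounding 100 ms
    ctx <- round(0.05 * fs)
    amp <- params$crackle$amp_ratio * local_rms((i0 - ctx):(i0 + ctx))
    idx <- i0:(i0 + length(tt) - 1L)
    keep <- idx >= 1L & idx <= n
    x[idx[keep]] <- x[idx[keep]] + amp * pulse[keep]
    events <- rbind(events, data.frame(type = "crackle", time_s = start,
                                       freq_hz = f0, duration_s = dur,
                                       amplitude = amp))
    list(x = x, events = events)
  }

  with_seed(params$seed + 131071L, {
    for (ci in seq_len(n_cycles) - 1L) {
      cycle_start <- ci * cycle
      if (params$wheeze$prob > 0 &&
          stats::runif(1) < params$wheeze$prob) {
        res <- add_wheeze(x, events, cycle_start)
        x <- res$x; events <- res$events
      }
      if (params$crackle$count > 0) {
        for (k in seq_len(stats::rpois(1, params$crackle$count))) {
          res <- add_crackle(x, events, cycle_start)
          x <- res$x; events <- res$events
        }
      }
    }
    if (nrow(events) == 0L) {
      # force one event so the unhealthy label is never vacuous
      cycle_start <- (sample.int(n_cycles, 1L) - 1L) * cycle
      res <- if (params$wheeze$prob > 0) add_wheeze(x, events, cycle_start)
             else add_crackle(x, events, cycle_start)
      x <- res$x; events <- res$events
    }
  })
  .finalize_synth(x, params, "unhealthy", events)
}

#' Generate a labeled synthetic corpus
#'
#' Draws per-recording parameters from realistic ranges with a seeded
#' generator — duration uniform in 5-30 s, respiratory rate uniform in 12-20
#' breaths/min, heart-sound contamination with probability 0.3, and for
#' unhealthy recordings a mixture of wheeze-dominant, crackle-dominant and
#' combined profiles with probabilities 0.55/0.25/0.20, approximating the
#' condition mix of a pulmonology cohort (obstructive disease — asthma,
#' COPD, bronchitis — is mostly wheeze-dominant; heart failure, fibrosis and
#' pneumonia present with crackles, sometimes alongside wheezes), with
#' wheeze amplitude ratio
#' uniform in 0.8-1.6 (clearly audible, on the order of the overall
#' breath-sound level, as expected in diagnosed obstructive disease),
#' crackle amplitude ratio uniform in 3-6 (sharp transients clearly
#' above the local breath sound, whose Gaussian peaks already reach ~3 RMS)
#' and 10-30 crackles per cycle (real crackles come in inspiratory
#' showers) — then
#' synthesizes each recording from its own derived seed. The default counts
#' (35 healthy, 77 unhealthy) mirror the class balance of a 112-subject
#' auscultation corpus.
#'
#' @param n_healthy,n_unhealthy Recording counts per class (>= 1).
#' @param seed Master seed; the whole corpus (manifest included) is a
#'   deterministic function of it.
#' @param base_params A [synth_params()] supplying the non-drawn defaults
#'   (noise band, SNR, event frequency ranges, ...).
#' @param wheeze_amp_range,crackle_amp_range Length-2 ranges the per-recording
#'   amplitude ratios are drawn from (degenerate ranges fix the value, useful
#'   for effect-size experiments).
#' @param profile_probs Length-3 probabilities of the wheeze / crackle /
#'   mixed unhealthy profiles.
#' @return List with `recordings` (list of [recording()]s), `manifest`
#'   (data.frame of all drawn parameters per recording) and `events`
#'   (ground-truth adventitious events across the corpus).
#' @export
generate_corpus <- function(n_healthy = 35, n_unhealthy = 77, seed = 42,
                            base_params = synth_params(),
                            wheeze_amp_range = c(0.8, 1.6),
                            crackle_amp_range = c(3, 6),
                            profile_probs = c(0.55, 0.25, 0.20)) {
  stopifnot(n_healthy >= 1, n_unhealthy >= 1)
  n <- n_healthy + n_unhealthy
  draws <- with_seed(seed, {
    data.frame(
      id = c(sprintf("healthy_%03d", seq_len(n_healthy)),
             sprintf("unhealthy_%03d", seq_len(n_unhealthy))),
      label = rep(c("healthy", "unhealthy"), c(n_healthy, n_unhealthy)),
      seed = sample.int(2147482647L, n),
      duration_s = stats::runif(n, 5, 30),
      breath_rate_bpm = stats::runif(n, 12, 20),
      heart = stats::runif(n) < 0.3,
      profile = c(rep(NA_character_, n_healthy),
                  sample(c("wheeze", "crackle", "mixed"), n_unhealthy,
                         replace = TRUE, prob = profile_probs)),
      wheeze_amp = stats::runif(n, wheeze_amp_range[1], wheeze_amp_range[2]),
      crackle_amp = stats::runif(n, crackle_amp_range[1],
                                 crackle_amp_range[2]),
      crackle_count = sample(10:30, n, replace = TRUE),
      bronchial_draw = stats::runif(n),
      snr_db = base_params$snr_db,
      stringsAsFactors = FALSE
    )
  })
  # bronchial breathing accompanies consolidation: common in crackle-dominant
  # disease (pneumonia, fibrosis), occasional in mixed presentations
  draws$bronchial <- !is.na(draws$profile) &
    ((draws$profile == "crackle" & draws$bronchial_draw < 0.7) |
     (draws$profile == "mixed" & draws$bronchial_draw < 0.3))
  draws$bronchial_draw <- NULL
  recordings <- vector("list", n)
  all_events <- list()
  for (i in seq_len(n)) {
    d <- draws[i, ]
    wheeze <- base_params$wheeze
    crackle <- base_params$crackle
    wheeze$amp_ratio <- d$wheeze_amp
    crackle$amp_ratio <- d$crackle_amp
    crackle$count <- d$crackle_count
    if (!is.na(d$profile)) {
      if (d$profile == "wheeze") crackle$count <- 0
      if (d$profile == "crackle") wheeze$prob <- 0
    }
    heart <- base_params$heart
    heart$include <- d$heart
    p <- synth_params(duration_s = d$duration_s,
                      breath_rate_bpm = d$breath_rate_bpm,
                      noise_band = base_params$noise_band,
                      wheeze = wheeze, crackle = crackle, heart = heart,
                      bronchial = d$bronchial,
                      snr_db = d$snr_db, rate = base_params$rate,
                      seed = d$seed, id = d$id)
    rec <- if (d$label == "healthy") synth_healthy(p) else synth_unhealthy(p)
    recordings[[i]] <- rec
    ev <- attr(rec, "events")
    if (nrow(ev) > 0) {
      ev$id <- d$id
      all_events[[length(all_events) + 1L]] <- ev
    }
  }
  events <- if (length(all_events) > 0) do.call(rbind, all_events)
            else cbind(.empty_events(), data.frame(id = character(0)))
  list(recordings = recordings, manifest = draws, events = events)
}
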
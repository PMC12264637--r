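test_that("mean-square energy matches hand evaluation", {
  expect_equal(signal_energy(c(1, 1, 1, 1)), 1.0)
  expect_equal(signal_energy(rep(0, 16)), 0.0)
  expect_equal(signal_energy(c(1, 2, 3)), 14 / 3)
})

test_that("zero-crossing rate counts strict sign changes only", {
  expect_equal(zero_crossing_rate(c(1, -1, 1, -1)), 1.0)
  expect_equal(zero_crossing_rate(c(2, 2, 2)), 0.0)
  expect_equal(zero_crossing_rate(c(1, -1, -1, 1)), 2 / 3)
  expect_equal(zero_crossing_rate(c(1, 0, -1)), 0.0)  # zero sample: no crossing
  expect_error(zero_crossing_rate(1), "at least 2")
})

test_that("band power recovers the flat PSD level of white noise", {
  set.seed(11)
  x <- rnorm(2^15)
  # unit-variance white noise at 4000 Hz: density = 1/2000 per Hz
  for (mode in filter_modes()) {
    bp <- band_power(x, mode, rate = 4000)
    expect_lt(abs(bp - 1 / 2000) / (1 / 2000), 0.20)
  }
  expect_equal(band_power(rep(0, 4096), filter_modes()$bell, rate = 4000), 0)
})

test_that("band power concentrates a tone in the right mode band", {
  x <- make_tone(300, dur = 4)
  p_dia <- band_power(x, filter_modes()$diaphragm)
  p_bell <- band_power(x, filter_modes()$bell)
  expect_gte(p_dia, 50 * p_bell)
  narrow <- filter_mode("narrow", 10, 11)
  expect_error(band_power(rnorm(256), narrow, rate = 4000, nfft = 256),
               "resolution")
})

test_that("spectral centroid locates tones, flat spectra and degenerate input", {
  tone <- make_tone(440, dur = 1)     # integer number of periods at 4000 Hz
  expect_lte(abs(spectral_centroid(tone) - 440), 4000 / length(tone$samples))

  impulse <- c(1, rep(0, 255))        # equal magnitude in every bin
  freqs <- (0:128) * 4000 / 256
  expect_equal(spectral_centroid(impulse, rate = 4000), mean(freqs))

  expect_equal(spectral_centroid(rep(0.7, 1000), rate = 4000), 0)  # DC only
  expect_warning(z <- spectral_centroid(rep(0, 10), rate = 4000),
                 "identically-zero")
  expect_equal(z, 0)
})

test_that("MFCC matches the independent reference implementation", {
  fs <- 4000
  n <- 0:1999
  x <- sin(2 * pi * 250 * n / fs) + 0.5 * sin(2 * pi * 640 * n / fs + 1)
  m <- mfcc_matrix(x, mfcc_config(), rate = fs)
  expect_equal(dim(m), c(48, 13))
  # frozen values from an independent NumPy implementation of the same
  # pinned definition (HTK mel, periodic Hann 25/10 ms, |FFT|^2, floor 1e-10,
  # orthonormal DCT-II, c1..c13)
  ref_grand <- -0.001286757401674
  ref_coef <- c(29.814693852663, -15.752740946167, -5.224395507766,
                -0.373125699286, -7.517147155121, -12.506485408894,
                -1.856601912603, 7.425390129626, 5.402236974804,
                -1.085392026265, -1.170913268581, 1.380147598172,
                1.447605523197)
  expect_lt(abs(mean(m) - ref_grand), 1e-6)
  expect_lt(max(abs(colMeans(m) - ref_coef)), 1e-6)
})

test_that("MFCC degenerate and scaling behavior is sane", {
  # all-zero input: log floor is constant across mel bands, and the DCT of a
  # constant has no energy in c1.. -> exactly 0 after reduction
  expect_lt(abs(mfcc_scalar(rep(0, 2000), rate = 4000)), 1e-8)
  set.seed(5)
  x <- rnorm(2000)
  m1 <- mfcc_scalar(x, rate = 4000)
  m2 <- mfcc_scalar(2 * x, rate = 4000)
  expect_true(is.finite(m1) && is.finite(m2))
  expect_error(mfcc_scalar(rnorm(50), rate = 4000), "shorter than")
  expect_error(mfcc_config(n_mels = 10, n_coeffs = 10), "n_coeffs < n_mels")
})

test_that("extract_features yields 15 canonical, deterministic, finite values", {
  rec <- synth_healthy(synth_params(duration_s = 6, seed = 7, id = "h7"))
  fv <- extract_features(rec)
  expect_length(fv, 15)
  expect_identical(names(fv), feature_names())
  expect_true(all(is.finite(fv)))
  zcrs <- fv[grep("_zcr$", names(fv))]
  expect_true(all(zcrs >= 0 & zcrs <= 1))
  cents <- fv[grep("_centroid$", names(fv))]
  expect_true(all(cents > 0 & cents < 2000))
  expect_identical(unclass(extract_features(rec)), unclass(fv))
  expect_identical(attr(fv, "id"), "h7")
})

test_that("feature extraction is amplitude invariant after normalization", {
  rec <- synth_healthy(synth_params(duration_s = 6, seed = 9))
  scaled <- recording(rec$samples * 0.37, rec$rate, id = rec$id,
                      label = rec$label)
  expect_equal(unclass(extract_features(rec)),
               unclass(extract_features(scaled)), tolerance = 1e-6)
})

test_that("centroid strictly increases when a high tone joins a low signal", {
  low <- make_tone(150, dur = 1)
  for (f_hi in c(700, 1100, 1500)) {
    mixed <- low$samples + 0.4 * make_tone(f_hi, dur = 1)$samples
    expect_gt(spectral_centroid(mixed, rate = 4000),
              spectral_centroid(low))
  }
})

test_that("energy agrees with the integrated Welch PSD (Parseval)", {
  set.seed(21)
  x <- rnorm(2^15)
  ps <- welch_psd(x, rate = 4000)
  integrated <- sum(ps$psd) * (ps$freq[2] - ps$freq[1])
  expect_lt(abs(integrated - signal_energy(x)) / signal_energy(x), 0.10)
})

test_that("the feature matrix has one ordered row per recording and survives CSV", {
  recs <- lapply(1:3, function(i) {
    synth_healthy(synth_params(duration_s = 5.5, seed = i,
                               id = sprintf("r%02d", i)))
  })
  recs[[2]]$label <- "unhealthy"
  tab <- build_feature_matrix(recs)
  expect_equal(dim(tab), c(3, 17))
  expect_identical(tab$id, c("r01", "r02", "r03"))
  expect_identical(tab$label, c("healthy", "unhealthy", "healthy"))

  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(tab, path)
  back <- read_feature_csv(path)
  expect_identical(names(back), names(tab))
  expect_lt(max(abs(as.matrix(back[, feature_names()]) -
                      as.matrix(tab[, feature_names()]))), 1e-12)

  recs[[3]]$id <- "r01"
  expect_error(build_feature_matrix(recs), "duplicate")
})
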
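test_that("a unit sinusoid integrates to its analytic power at its frequency", {
  t <- (seq_len(125 * 16) - 1) / 125
  psd <- welch_psd(sin(2 * pi * 10 * t), fs = 125)
  expect_equal(psd$freq[which.max(psd$power)], 10, tolerance = 1e-9)
  total <- sum(psd$power) * diff(psd$freq[1:2])
  expect_equal(total, 0.5, tolerance = 0.025)
  expect_equal(band_power(psd, "alpha"), 0.5, tolerance = 0.025)
  expect_lt(band_power(psd, "theta"), 0.01)
  expect_lt(band_power(psd, "beta"), 0.01)
})

test_that("white noise has a flat density of 2/fs and bandwidth-proportional band powers", {
  withr::with_seed(11, x <- rnorm(60000))
  psd <- welch_psd(x, fs = 125)
  inband <- psd$power[psd$freq >= 1 & psd$freq <= 60]
  expect_equal(mean(inband), 2 / 125, tolerance = 0.05)
  ratio <- band_power(psd, "beta") / band_power(psd, "theta")
  expect_equal(ratio, (25 - 14) / (8 - 4), tolerance = 0.15)
})

test_that("degenerate inputs are handled: constants, zeros, coarse grids", {
  psd <- welch_psd(rep(3, 1000), fs = 125)
  expect_equal(psd$freq[which.max(psd$power)], 0)
  # all but Hamming leakage sits at DC
  expect_lt(sum(psd$power[psd$freq > 2]) / sum(psd$power), 1e-4)

  zero <- welch_psd(rep(0, 1000), fs = 125)
  expect_equal(band_power(zero, "alpha"), 0)

  coarse <- tibble::tibble(freq = seq(0, 62.5, by = 5), power = rep(1, 13))
  expect_error(band_power(coarse, "delta"), "too coarse")
  expect_error(welch_psd(rep(NA_real_, 100), 125), "NA")
  expect_error(welch_psd(rnorm(50), 125, segment_length = 100), "shorter")
})

test_that("welch equals an independent brute-force windowed periodogram", {
  withr::with_seed(12, x <- rnorm(64))
  psd <- welch_psd(x, fs = 32, segment_length = 64, overlap = 0)
  w <- 0.54 - 0.46 * cos(2 * pi * seq_len(64) / 65)
  ref <- brute_periodogram(x, w, fs = 32)
  expect_lt(max(abs(psd$power - ref)) / max(ref), 1e-10)

  # rectangular window variant
  psd_r <- welch_psd(x, fs = 32, segment_length = 64, overlap = 0, window = "rectangular")
  ref_r <- brute_periodogram(x, rep(1, 64), fs = 32)
  expect_lt(max(abs(psd_r$power - ref_r)) / max(ref_r), 1e-10)
})

test_that("PSD scales quadratically with amplitude", {
  withr::with_seed(13, x <- rnorm(2000))
  p1 <- welch_psd(x, 125)
  p5 <- welch_psd(5 * x, 125)
  expect_equal(p5$power, 25 * p1$power, tolerance = 1e-10)
})

test_that("band powers satisfy Parseval against the filtered-signal variance", {
  withr::with_seed(14, raw <- rnorm(125 * 120))
  rec <- eeg_recording(
    tibble::tibble(time_s = (seq_along(raw) - 1) / 125, F8 = raw),
    fs = 125
  )
  x <- preprocess_recording(rec)$data$F8
  psd <- welch_psd(x, 125)
  total <- sum(vapply(eeg_bands()$band, function(b) band_power(psd, b), numeric(1)))
  expect_equal(total, stats::var(x), tolerance = 0.05 * stats::var(x))
})

test_that("the spectrogram localizes a frequency switch in time", {
  fs <- 125
  t1 <- (seq_len(fs * 30) - 1) / fs
  x <- c(sin(2 * pi * 10 * t1), sin(2 * pi * 20 * t1))
  sg <- spectrogram(x, fs, window_s = 2, overlap = 0.5)
  peaks <- sg |>
    dplyr::group_by(.data$time) |>
    dplyr::summarise(peak = .data$freq[which.max(.data$power)], .groups = "drop")
  expect_true(all(peaks$peak[peaks$time < 28] == 10))
  expect_true(all(peaks$peak[peaks$time > 32] == 20))

  zero <- spectrogram(rep(0, fs * 25), fs, window_s = 10)
  expect_true(all(zero$power == 0))
  expect_error(spectrogram(rnorm(100), fs, window_s = 10), "longer than signal")
})

test_that("an alert synthetic epoch is beta-dominant in the spectrogram", {
  states <- rep(0L, 125 * 40)
  x <- synthesize_channel(states, 125,
    artifacts = NULL, gain_jitter_sd = 0,
    depth_jitter_sd = 0, bursts = NULL, beta_dropout_rate_per_min = 0, seed = 21
  )
  sg <- spectrogram(x, 125, window_s = 10)
  row_power <- function(lo, hi) mean(sg$power[sg$freq >= lo & sg$freq < hi])
  expect_gt(row_power(14, 25), row_power(8, 14))
})
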
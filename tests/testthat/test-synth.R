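# A gain profile with all power in a single band, bypassing the constructor's
# physiological ordering checks (test-only degenerate object).
single_band_gains <- function(band) {
  g <- c(delta = 0, theta = 0, alpha = 0, beta = 0)
  g[band] <- 1
  structure(list(alert = g, drowsy = g), class = "band_gain_profile")
}

clean_channel <- function(states, gains, fs = 125, seed = 1, ...) {
  synthesize_channel(states, fs,
    gains = gains, artifacts = NULL,
    gain_jitter_sd = 0, depth_jitter_sd = 0, bursts = NULL,
    beta_dropout_rate_per_min = 0, seed = seed, ...
  )
}

test_that("state sequences have the right length, alphabet and reproducibility", {
  s <- generate_state_sequence(1800, 60, 120, fs_label = 1, seed = 7)
  expect_length(s, 1800)
  expect_true(all(s %in% c(0L, 1L)))
  expect_setequal(unique(s), c(0L, 1L))
  expect_identical(
    as.integer(generate_state_sequence(600, 60, 80, fs_label = 5, seed = 3)),
    as.integer(generate_state_sequence(600, 60, 80, fs_label = 5, seed = 3))
  )
  # dwell floor: no run shorter than 10 s except possibly the truncated last
  runs <- rle(as.integer(s))$lengths
  expect_true(all(utils::head(runs, -1) >= 10))
})

test_that("degenerate dwell limits and invalid parameters behave as specified", {
  s <- generate_state_sequence(300, 60, Inf, fs_label = 1, start_state = 1, seed = 1)
  expect_true(all(s == 1L))
  expect_error(generate_state_sequence(-5, 60, 80), "positive")
  expect_error(generate_state_sequence(100, 5, 80), "window floor")
})

test_that("long-run drowsy fraction matches the renewal-theory value", {
  fracs <- vapply(seq_len(10000), function(i) {
    mean(generate_state_sequence(600, 60, 80, fs_label = 1, seed = 50000L + i))
  }, numeric(1))
  se <- stats::sd(fracs) / sqrt(length(fracs))
  expect_lt(abs(mean(fracs) - 80 / 140), 3 * se)
})

test_that("single-band gain profiles put >=90% of in-band power in that band", {
  states <- rep(0L, 125 * 40)
  for (band in c("delta", "theta", "alpha", "beta")) {
    x <- clean_channel(states, single_band_gains(band))
    psd <- welch_psd(x, 125)
    bd <- eeg_bands()
    inband <- band_power(psd, band)
    total <- band_power(psd, c(0.5, 40))
    expect_gt(inband / total, 0.9)
  }
})

test_that("zero gains and no artifacts give the all-zero signal", {
  states <- rep(c(0L, 1L), each = 1250)
  g <- structure(
    list(
      alert = c(delta = 0, theta = 0, alpha = 0, beta = 0),
      drowsy = c(delta = 0, theta = 0, alpha = 0, beta = 0)
    ),
    class = "band_gain_profile"
  )
  expect_equal(clean_channel(states, g), rep(0, length(states)))
})

test_that("line noise produces a 50 Hz PSD peak that the notch removes", {
  states <- rep(0L, 125 * 60)
  art <- artifact_spec(
    line_freqs = 50, line_amp = 3, breathing_amp = 0,
    drift_amp = 0, background_amp = 0, sensor_noise_amp = 0.2
  )
  x <- synthesize_channel(states, 125,
    artifacts = art, gain_jitter_sd = 0,
    depth_jitter_sd = 0, bursts = NULL, beta_dropout_rate_per_min = 0, seed = 2
  )
  psd_raw <- welch_psd(x, 125, segment_length = 500)
  peak_freq <- psd_raw$freq[which.max(psd_raw$power)]
  expect_equal(peak_freq, 50, tolerance = 0.01)

  rec <- eeg_recording(
    tibble::tibble(time_s = (seq_along(x) - 1) / 125, F8 = x),
    fs = 125
  )
  clean <- preprocess_recording(rec)
  psd_clean <- welch_psd(clean$data$F8, 125, segment_length = 500)
  at50 <- function(p) sum(p$power[abs(p$freq - 50) <= 0.5])
  expect_lt(at50(psd_clean) / at50(psd_raw), 1e-3)
})

test_that("sessions are reproducible and carry the configured montage", {
  cfg <- session_config(duration_s = 60)
  a <- generate_session(cfg, seed = 1)
  b <- generate_session(cfg, seed = 1)
  expect_identical(a$data, b$data)
  c2 <- generate_session(cfg, seed = 2)
  expect_false(isTRUE(all.equal(a$data$F8, c2$data$F8)))
  expect_error(session_config(channels = c("F8", "Cz")), "valid montage")
  expect_error(session_config(channels = "F7", coi = "F8"), "configured channels")
})

test_that("the default session matches the acquisition protocol and class balance", {
  rec <- generate_session(session_config(), seed = 42)
  expect_equal(rec$fs, 125)
  expect_equal(rec$channels, c("Fp1", "Fp2", "F7", "F8", "O1", "O2"))
  expect_equal(nrow(rec$data), 1800 * 125)
  wins <- segment_windows(rec)
  labels <- assign_window_label(wins$label_fraction[wins$channel == "F8"])
  expect_gte(mean(labels == 1), 0.2)
  expect_gte(mean(labels == 0), 0.2)
})
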
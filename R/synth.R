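#' Alternating alert/drowsy state sequence
#'
#' Generates a binary state sequence (0 = alert, 1 = drowsy) on a label grid,
#' as alternating runs whose dwell times follow a shifted-exponential
#' distribution with a floor of one analysis window (10 s): dwell =
#' floor + Exp(mean - floor). When `start_state` is `NULL` the process is
#' started in its stationary regime (state picked proportional to mean dwell,
#' first residual dwell from the equilibrium distribution), so the expected
#' drowsy fraction equals `dwell_mean_drowsy / (dwell_mean_alert +
#' dwell_mean_drowsy)` at any duration.
#'
#' @param duration_s Session duration in seconds (> 0).
#' @param dwell_mean_alert,dwell_mean_drowsy Mean dwell time of each state in
#'   seconds; both must be at least `min_dwell`. May be `Inf` (the state never
#'   ends once entered).
#' @param fs_label Label grid rate in Hz; defaults to 125, the signal rate.
#' @param min_dwell Dwell-time floor in seconds (default 10, one analysis
#'   window).
#' @param start_state Force the initial state (0 or 1) with a full first
#'   dwell, or `NULL` (default) for a stationary start.
#' @param seed Optional integer seed; identical seeds give identical
#'   sequences.
#' @return Integer vector of 0/1 labels of length `duration_s * fs_label`,
#'   with attributes `fs_label`, `dwell_mean_alert`, `dwell_mean_drowsy`.
#' @examples
#' s <- generate_state_sequence(1800, 60, 80, fs_label = 1, seed = 7)
#' mean(s) # drowsy fraction, around 80 / (60 + 80)
#' @export
generate_state_sequence <- function(duration_s, dwell_mean_alert = 60,
                                    dwell_mean_drowsy = 80, fs_label = 125,
                                    min_dwell = 10, start_state = NULL,
                                    seed = NULL) {
  if (!is.numeric(duration_s) || duration_s <= 0) {
    stop("`duration_s` must be positive", call. = FALSE)
  }
  means <- c(alert = dwell_mean_alert, drowsy = dwell_mean_drowsy)
  if (any(means < min_dwell) || any(means <= 0)) {
    stop("dwell means must be at least the ", min_dwell, " s window floor",
      call. = FALSE
    )
  }
  gen <- function() {
    draw_dwell <- function(m) {
      if (is.infinite(m)) {
        return(Inf)
      }
      if (m == min_dwell) {
        return(min_dwell)
      }
      min_dwell + stats::rexp(1L, rate = 1 / (m - min_dwell))
    }
    # equilibrium residual of the shifted exponential: density S(x)/m
    draw_residual <- function(m) {
      if (is.infinite(m)) {
        return(Inf)
      }
      if (stats::runif(1L) < min_dwell / m) {
        stats::runif(1L, 0, min_dwell)
      } else {
        min_dwell + stats::rexp(1L, rate = 1 / (m - min_dwell))
      }
    }
    if (is.null(start_state)) {
      if (is.infinite(means["alert"]) && is.infinite(means["drowsy"])) {
        state <- stats::rbinom(1L, 1L, 0.5)
      } else if (is.infinite(means["drowsy"])) {
        state <- 1L
      } else if (is.infinite(means["alert"])) {
        state <- 0L
      } else {
        state <- stats::rbinom(1L, 1L, means["drowsy"] / sum(means))
      }
      first <- draw_residual(means[state + 1L])
    } else {
      state <- as.integer(start_state)
      stopifnot(state %in% c(0L, 1L))
      first <- draw_dwell(means[state + 1L])
    }
    t_edges <- numeric(0)
    vals <- integer(0)
    t_cum <- 0
    dwell <- first
    repeat {
      t_cum <- t_cum + dwell
      vals <- c(vals, state)
      t_edges <- c(t_edges, t_cum)
      if (t_cum >= duration_s) break
      state <- 1L - state
      dwell <- draw_dwell(means[state + 1L])
    }
    n <- as.integer(round(duration_s * fs_label))
    tt <- (seq_len(n) - 1) / fs_label
    vals[findInterval(tt, c(0, t_edges), left.open = TRUE, rightmost.closed = TRUE)]
  }
  labels <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  structure(as.integer(labels),
    fs_label = fs_label,
    dwell_mean_alert = dwell_mean_alert,
    dwell_mean_drowsy = dwell_mean_drowsy
  )
}

#' State-dependent spectral gain profile
#'
#' Linear amplitude gains per band and physiological state for the synthetic
#' generator. The alert profile is beta-dominant; the drowsy profile shifts
#' power into alpha and the slow-wave (theta, delta) bands.
#'
#' @param alert,drowsy Named numeric vectors with positive entries `delta`,
#'   `theta`, `alpha`, `beta`.
#' @return A list of class `band_gain_profile`.
#' @export
band_gain_profile <- function(alert = c(delta = 0.75, theta = 0.65, alpha = 0.62, beta = 1.0),
                              drowsy = c(delta = 1.2, theta = 0.95, alpha = 1.05, beta = 0.9)) {
  need <- c("delta", "theta", "alpha", "beta")
  for (nm in c("alert", "drowsy")) {
    g <- get(nm)
    if (!all(need %in% names(g))) {
      stop("`", nm, "` gains must name ", paste(need, collapse = ", "), call. = FALSE)
    }
    if (any(g[need] <= 0)) stop("all gains must be positive", call. = FALSE)
  }
  if (!all(drowsy[c("alpha", "theta", "delta")] > drowsy["beta"])) {
    stop("drowsy profile must have alpha/theta/delta gains above its beta gain",
      call. = FALSE
    )
  }
  if (alert["beta"] <= alert["alpha"]) {
    stop("alert profile must have beta gain above its alpha gain", call. = FALSE)
  }
  structure(list(alert = alert[need], drowsy = drowsy[need]),
    class = "band_gain_profile"
  )
}

#' Artifact and background specification for the synthetic generator
#'
#' Mirrors the nuisance components the preprocessing cascade is designed to
#' remove: power-line interference, a breathing oscillation, sub-0.01 Hz
#' drift, plus a 1/f spectral background.
#'
#' @param line_freqs Power-line frequencies (Hz). Default `c(50, 60)`.
#' @param line_amp Line amplitude (relative units). Default 1.
#' @param breathing_band Breathing band (Hz); a sinusoid at its midpoint is
#'   injected. Default `c(0.3, 0.4)`.
#' @param breathing_amp Breathing amplitude. Default 2.
#' @param drift_freq Drift frequency (Hz, below 0.01). Default 0.005.
#' @param drift_amp Drift amplitude. Default 5.
#' @param background_exponent Slope of the 1/f^exponent background. Default 1.
#' @param background_amp Background amplitude scale. Default 0.5.
#' @param sensor_noise_amp Amplitude of the flat (white) instrumentation
#'   noise floor typical of dry-electrode amplifiers. Default 0.8.
#' @return A list of class `artifact_spec`.
#' @export
artifact_spec <- function(line_freqs = c(50, 60), line_amp = 1,
                          breathing_band = c(0.3, 0.4), breathing_amp = 2,
                          drift_freq = 0.005, drift_amp = 5,
                          background_exponent = 1, background_amp = 0.5,
                          sensor_noise_amp = 0.8) {
  stopifnot(
    length(breathing_band) == 2L, breathing_band[1] < breathing_band[2],
    drift_freq < 0.01, background_exponent >= 0
  )
  structure(
    list(
      line_freqs = line_freqs, line_amp = line_amp,
      breathing_band = breathing_band, breathing_amp = breathing_amp,
      drift_freq = drift_freq, drift_amp = drift_amp,
      background_exponent = background_exponent,
      background_amp = background_amp,
      sensor_noise_amp = sensor_noise_amp
    ),
    class = "artifact_spec"
  )
}

#' Alert-state engagement burst specification
#'
#' Transient power bursts during alert periods (mental engagement while
#' driving): raised-cosine amplitude bumps at Poisson arrival times,
#' multiplying every band's gain, with a dominant boost in beta and a mild
#' broadband component. Alert-state beta is largely phasic, riding on these
#' engagement episodes rather than on a tonic elevation.
#'
#' @param rate_per_min Poisson arrival rate during alert time (1/min).
#' @param duration_s Bump duration (s).
#' @param gains Named per-band peak amplitude multipliers.
#' @return A list usable as the `bursts` argument of [synthesize_channel()].
#' @export
alert_burst_spec <- function(rate_per_min = 10, duration_s = 5,
                             gains = c(delta = 1.1, theta = 1.1, alpha = 1.1, beta = 2.5)) {
  stopifnot(rate_per_min >= 0, duration_s > 0, all(gains >= 1))
  list(rate_per_min = rate_per_min, duration_s = duration_s, gains = gains)
}

# 1/f^a background noise via FFT spectral shaping.
pink_noise <- function(n, exponent) {
  white <- stats::rnorm(n)
  if (exponent == 0) {
    return(white)
  }
  X <- stats::fft(white)
  k <- c(1, seq_len(n - 1)) # avoid dividing DC by zero
  shape <- 1 / k^(exponent / 2)
  shape[1] <- 0
  # keep conjugate symmetry by shaping symmetrically around Nyquist
  half <- floor(n / 2)
  shape[(n - half + 1):n] <- rev(shape[2:(half + 1)])
  x <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Synthesize one EEG channel from a state sequence
#'
#' Builds the signal as a sum over bands of band-limited Gaussian noise
#' (white noise through a zero-phase 4th-order Butterworth band-pass) scaled by the
#' state- and band-dependent gain, plus the artifact components and a 1/f
#' background. State transitions are smoothed with a 0.5-s raised-cosine
#' cross-fade so band edges do not ring.
#'
#' @param states Integer 0/1 vector on the sample grid (one label per
#'   sample), e.g. from [generate_state_sequence()].
#' @param fs Sampling rate (Hz); must be at least twice the highest generated
#'   frequency component.
#' @param gains A [band_gain_profile()].
#' @param contrast Channel contrast multiplier (>= 0): an exponent on each
#'   band's drowsy/alert gain ratio, so `contrast = 2` doubles every band's
#'   log-scale state contrast while leaving the alert profile untouched.
#'   The channel of interest gets the largest value.
#' @param bursts Alert-state engagement bursts: `NULL` to disable, or a list
#'   with `rate_per_min` (Poisson arrival rate during alert periods),
#'   `duration_s` (raised-cosine bump length) and `gains` (named per-band
#'   amplitude multipliers at the bump peak; beta-dominant by default,
#'   mirroring the phasic beta elevation of engaged wakefulness). Default
#'   `alert_burst_spec()`.
#' @param beta_dropout_rate_per_min,beta_dropout_s,beta_dropout_gain
#'   Transient beta desynchronization events: brief, state-independent
#'   collapses of beta-band amplitude (alpha blocking / momentary electrode
#'   decoupling), at Poisson times. Defaults: 1 per minute, 2 s long,
#'   amplitude factor 0.1. Set the rate to 0 to disable.
#' @param artifacts An [artifact_spec()], or `NULL` to disable all artifact
#'   and background components.
#' @param amp_uV Overall output scale in microvolts per unit gain. Default 10.
#' @param crossfade_s Cross-fade length at state transitions (s). Default 0.5.
#' @param gain_jitter_sd Log-scale standard deviation of the slow multiplicative
#'   gain fluctuation per band (default 0.28); emulates the within-state
#'   amplitude variability of real EEG rhythms. The delta/theta/alpha
#'   fluctuations share a common component (correlation
#'   `slow_jitter_correlation`), reflecting their joint thalamocortical
#'   modulation; beta fluctuates independently. Set 0 to disable.
#' @param slow_jitter_correlation Correlation of the slow-band gain
#'   fluctuations (default 0.5).
#' @param jitter_timescale_s Correlation time of the gain fluctuation (s).
#'   Default 20.
#' @param depth_jitter_sd Standard deviation of the continuous vigilance-depth
#'   fluctuation around the labelled state (default 0.2): the latent arousal
#'   level drifts between fully alert (0) and deeply drowsy (1), moving all
#'   band gains coherently along the beta-to-slow-wave seesaw. Default 0.1.
#'   Set 0 for sharp binary states.
#' @param seed Optional integer seed.
#' @return Numeric vector of samples (microvolts), same length as `states`.
#' @export
synthesize_channel <- function(states, fs, gains = band_gain_profile(),
                               contrast = 1, artifacts = artifact_spec(),
                               amp_uV = 10, crossfade_s = 0.5,
                               gain_jitter_sd = 0.28, jitter_timescale_s = 20,
                               slow_jitter_correlation = 0.5,
                               depth_jitter_sd = 0.1,
                               bursts = alert_burst_spec(),
                               beta_dropout_rate_per_min = 1,
                               beta_dropout_s = 2,
                               beta_dropout_gain = 0.1, seed = NULL) {
  n <- length(states)
  if (n == 0L) stop("empty state sequence", call. = FALSE)
  stopifnot(all(states %in% c(0L, 1L)), contrast >= 0)
  max_f <- 25 # highest band-pass edge (beta)
  if (!is.null(artifacts)) max_f <- max(max_f, artifacts$line_freqs)
  if (fs < 2 * max_f) {
    stop("fs = ", fs, " Hz cannot represent components up to ", max_f, " Hz",
      call. = FALSE
    )
  }
  build <- function() {
    bands <- eeg_bands()
    bands <- bands[bands$band %in% names(gains$alert), ]
    # smooth state indicator for cross-faded gain envelopes
    L <- max(1L, as.integer(round(crossfade_s * fs)))
    taper <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1))
    taper <- taper / sum(taper)
    smooth_state <- as.numeric(stats::filter(states, taper, sides = 2))
    smooth_state[is.na(smooth_state)] <- states[is.na(smooth_state)]

    # latent arousal level: labelled state plus slow vigilance-depth drift
    arousal <- smooth_state
    if (depth_jitter_sd > 0) {
      rho_d <- exp(-1 / (30 * fs))
      dn <- as.numeric(stats::filter(stats::rnorm(n), rho_d, method = "recursive"))
      arousal <- pmin(pmax(arousal + dn / stats::sd(dn) * depth_jitter_sd, -0.25), 1.25)
    }

    # engagement bursts: raised-cosine bumps at Poisson times, gated to alert
    burst_env <- numeric(n)
    if (!is.null(bursts) && bursts$rate_per_min > 0) {
      n_burst <- stats::rpois(1L, bursts$rate_per_min * n / fs / 60)
      if (n_burst > 0) {
        Lb <- max(2L, as.integer(round(bursts$duration_s * fs)))
        bump <- 0.5 - 0.5 * cos(2 * pi * seq_len(Lb) / (Lb + 1))
        for (s0 in sample.int(n, n_burst, replace = TRUE)) {
          e0 <- min(n, s0 + Lb - 1L)
          burst_env[s0:e0] <- pmax(burst_env[s0:e0], bump[seq_len(e0 - s0 + 1L)])
        }
      }
      burst_env <- burst_env * pmax(1 - smooth_state, 0) # alert periods only
    }

    # transient beta desynchronization, independent of the labelled state
    dropout_env <- numeric(n)
    if (beta_dropout_rate_per_min > 0) {
      n_drop <- stats::rpois(1L, beta_dropout_rate_per_min * n / fs / 60)
      if (n_drop > 0) {
        Ld <- max(2L, as.integer(round(beta_dropout_s * fs)))
        bump <- 0.5 - 0.5 * cos(2 * pi * seq_len(Ld) / (Ld + 1))
        for (s0 in sample.int(n, n_drop, replace = TRUE)) {
          e0 <- min(n, s0 + Ld - 1L)
          dropout_env[s0:e0] <- pmax(dropout_env[s0:e0], bump[seq_len(e0 - s0 + 1L)])
        }
      }
    }

    ar_noise <- function() {
      rho <- exp(-1 / (jitter_timescale_s * fs))
      x <- as.numeric(stats::filter(stats::rnorm(n), rho, method = "recursive"))
      x / stats::sd(x)
    }
    common_slow <- if (gain_jitter_sd > 0) ar_noise() else NULL

    out <- numeric(n)
    for (i in seq_len(nrow(bands))) {
      bname <- bands$band[i]
      bp <- signal::butter(4, c(bands$lo[i], bands$hi[i]) / (fs / 2), "pass")
      carrier <- signal::filtfilt(signal::Arma(b = bp$b, a = bp$a), stats::rnorm(n))
      g_alert <- gains$alert[[bname]]
      # the channel contrast amplifies the slow-wave/alpha response (the
      # spatially localized drowsiness signature); beta suppression is
      # treated as spatially uniform
      expo <- if (bname == "beta") 1 else contrast
      g_drowsy <- if (g_alert > 0) {
        g_alert * (gains$drowsy[[bname]] / g_alert)^expo
      } else {
        gains$drowsy[[bname]]
      }
      env <- pmax(g_alert + (g_drowsy - g_alert) * arousal, 0)
      if (!is.null(bursts) && any(burst_env > 0)) {
        env <- env * (1 + burst_env * (bursts$gains[[bname]] - 1))
      }
      if (bname == "beta" && any(dropout_env > 0)) {
        env <- env * (1 + dropout_env * (beta_dropout_gain - 1))
      }
      if (gain_jitter_sd > 0) {
        # slow lognormal amplitude fluctuation, AR(1)-smoothed, unit mean;
        # the slow bands share a common component
        ar <- if (bname == "beta") {
          ar_noise()
        } else {
          r <- slow_jitter_correlation
          r * common_slow + sqrt(1 - r^2) * ar_noise()
        }
        ar <- ar * gain_jitter_sd
        env <- env * exp(ar - gain_jitter_sd^2 / 2)
      }
      out <- out + env * carrier
    }
    if (!is.null(artifacts)) {
      tt <- (seq_len(n) - 1) / fs
      a <- artifacts
      for (f0 in a$line_freqs) {
        if (f0 < fs / 2 && a$line_amp > 0) {
          out <- out + a$line_amp * sin(2 * pi * f0 * tt + stats::runif(1, 0, 2 * pi))
        }
      }
      if (a$breathing_amp > 0) {
        fb <- mean(a$breathing_band)
        out <- out + a$breathing_amp * sin(2 * pi * fb * tt + stats::runif(1, 0, 2 * pi))
      }
      if (a$drift_amp > 0) {
        out <- out + a$drift_amp * sin(2 * pi * a$drift_freq * tt + stats::runif(1, 0, 2 * pi))
      }
      if (a$background_amp > 0 && n > 4) {
        out <- out + a$background_amp * pink_noise(n, a$background_exponent)
      }
      if (a$sensor_noise_amp > 0) {
        out <- out + a$sensor_noise_amp * stats::rnorm(n)
      }
    }
    out * amp_uV
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

#' Synthetic session configuration
#'
#' Bundles every generator parameter for one recording session. Defaults
#' reproduce the study conditions: the six-channel 10--20 montage (Fp1, Fp2,
#' F7, F8, O1, O2) at 125 Hz, 30-minute sessions, dwell means of 60 s alert /
#' 80 s drowsy (57.1% expected drowsy prevalence), and F8 as the designated
#' channel of interest with contrast 2.
#'
#' @param channels Channel names; must come from the supported montage.
#' @param duration_s Session length in seconds. Default 1800.
#' @param fs Sampling rate (Hz). Default 125.
#' @param dwell_mean_alert,dwell_mean_drowsy Mean state dwell times (s).
#' @param gains A [band_gain_profile()].
#' @param artifacts An [artifact_spec()] or `NULL`.
#' @param coi Designated channel of interest (must be in `channels`).
#' @param coi_contrast Contrast multiplier for the channel of interest.
#' @param amp_uV Output scale (microvolts per unit gain).
#' @param gain_jitter_sd,jitter_timescale_s,depth_jitter_sd,bursts
#'   Within-session gain fluctuation, vigilance-depth drift and alert
#'   engagement bursts, see [synthesize_channel()].
#' @param beta_dropout_rate_per_min Rate of transient beta desynchronization
#'   events, see [synthesize_channel()].
#' @param subject_gain_sd Log-scale standard deviation of the per-subject
#'   multiplicative perturbation of every state/band gain (default 0.08);
#'   emulates between-subject differences in spectral contrast. Set 0 to
#'   disable.
#' @param subject_beta_sd Extra log-scale standard deviation of the
#'   per-subject drowsy beta gain (default 0.2): the amount of beta
#'   suppression during drowsiness is strongly subject-dependent, so
#'   beta-denominated power ratios are less consistent across a pooled
#'   cohort than the band powers themselves.
#' @param subject_id Subject identifier.
#' @return A list of class `session_config`.
#' @export
session_config <- function(channels = c("Fp1", "Fp2", "F7", "F8", "O1", "O2"),
                           duration_s = 1800, fs = 125,
                           dwell_mean_alert = 60, dwell_mean_drowsy = 80,
                           gains = band_gain_profile(),
                           artifacts = artifact_spec(),
                           coi = "F8", coi_contrast = 2,
                           amp_uV = 10, gain_jitter_sd = 0.28,
                           jitter_timescale_s = 20,
                           slow_jitter_correlation = 0.5,
                           depth_jitter_sd = 0.1,
                           bursts = alert_burst_spec(),
                           beta_dropout_rate_per_min = 1,
                           subject_gain_sd = 0.08, subject_beta_sd = 0.2,
                           subject_id = "S01") {
  montage <- c("Fp1", "Fp2", "F7", "F8", "O1", "O2")
  bad <- setdiff(channels, montage)
  if (length(channels) == 0L || length(bad) > 0L) {
    stop("unknown channel(s) ", paste(bad, collapse = ", "),
      "; valid montage: ", paste(montage, collapse = ", "),
      call. = FALSE
    )
  }
  if (!coi %in% channels) {
    stop("`coi` (", coi, ") must be one of the configured channels", call. = FALSE)
  }
  structure(
    list(
      channels = channels, duration_s = duration_s, fs = fs,
      dwell_mean_alert = dwell_mean_alert,
      dwell_mean_drowsy = dwell_mean_drowsy,
      gains = gains, artifacts = artifacts,
      coi = coi, coi_contrast = coi_contrast,
      amp_uV = amp_uV, gain_jitter_sd = gain_jitter_sd,
      jitter_timescale_s = jitter_timescale_s,
      slow_jitter_correlation = slow_jitter_correlation,
      depth_jitter_sd = depth_jitter_sd, bursts = bursts,
      beta_dropout_rate_per_min = beta_dropout_rate_per_min,
      subject_gain_sd = subject_gain_sd, subject_beta_sd = subject_beta_sd,
      subject_id = subject_id
    ),
    class = "session_config"
  )
}

#' Generate a labelled synthetic EEG session
#'
#' All channels share a single alert/drowsy state sequence (sampled on the
#' signal grid), each synthesized independently via [synthesize_channel()];
#' the designated channel of interest carries the strongest state contrast.
#'
#' @param config A [session_config()].
#' @param seed Optional integer seed; all per-channel draws derive from it,
#'   so identical seeds give bit-identical recordings.
#' @return A labelled [eeg_recording()].
#' @examples
#' rec <- generate_session(session_config(duration_s = 120), seed = 1)
#' rec
#' @export
generate_session <- function(config = session_config(), seed = NULL) {
  stopifnot(inherits(config, "session_config"))
  derive <- function(i) {
    if (is.null(seed)) NULL else (as.integer(seed) + 1000003L * i) %% 2147483629L
  }
  states <- generate_state_sequence(
    config$duration_s, config$dwell_mean_alert, config$dwell_mean_drowsy,
    fs_label = config$fs, seed = derive(0L)
  )
  # per-subject perturbation of the gain profile (validation bypassed on
  # purpose: a perturbed profile may not satisfy the nominal orderings)
  gains <- config$gains
  if (config$subject_gain_sd > 0 || config$subject_beta_sd > 0) {
    perturb <- function(g) {
      g * exp(stats::rnorm(length(g), -config$subject_gain_sd^2 / 2, config$subject_gain_sd))
    }
    make_gains <- function() {
      g <- list(alert = perturb(gains$alert), drowsy = perturb(gains$drowsy))
      if (config$subject_beta_sd > 0) {
        # subject-specific depth of beta suppression: pull the drowsy beta
        # gain toward (or past) the alert level by a random amount
        s <- config$subject_beta_sd
        g$drowsy[["beta"]] <- g$drowsy[["beta"]] * exp(stats::rnorm(1, -s^2 / 2, s))
      }
      structure(g, class = "band_gain_profile")
    }
    gains <- if (is.null(seed)) {
      make_gains()
    } else {
      withr::with_seed(derive(101L), make_gains())
    }
  }
  n <- length(states)
  data <- tibble::tibble(time_s = (seq_len(n) - 1) / config$fs)
  for (i in seq_along(config$channels)) {
    ch <- config$channels[i]
    contrast <- if (ch == config$coi) config$coi_contrast else 1
    data[[ch]] <- synthesize_channel(
      states, config$fs,
      gains = gains, contrast = contrast,
      artifacts = config$artifacts, amp_uV = config$amp_uV,
      gain_jitter_sd = config$gain_jitter_sd,
      jitter_timescale_s = config$jitter_timescale_s,
      slow_jitter_correlation = config$slow_jitter_correlation,
      depth_jitter_sd = config$depth_jitter_sd,
      bursts = config$bursts,
      beta_dropout_rate_per_min = config$beta_dropout_rate_per_min,
      seed = derive(i)
    )
  }
  data$label <- as.integer(states)
  eeg_recording(data, fs = config$fs, subject_id = config$subject_id)
}
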
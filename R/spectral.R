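#' Canonical EEG frequency bands
#'
#' The five bands tiling the retained 0.5--40 Hz range under the half-open
#' convention `[lo, hi)`: delta 0.5--4, theta 4--8, alpha 8--14, beta 14--25
#' and gamma 25--40 Hz. Drowsiness onset shows as a power shift from beta
#' into alpha and the slow-wave (theta, delta) bands.
#'
#' @return A tibble with columns `band`, `lo`, `hi` (Hz).
#' @export
eeg_bands <- function() {
  tibble::tibble(
    band = c("delta", "theta", "alpha", "beta", "gamma"),
    lo = c(0.5, 4, 8, 14, 25),
    hi = c(4, 8, 14, 25, 40)
  )
}

#' Welch power spectral density estimate
#'
#' Averaged modified periodograms over Hamming-windowed, 50%-overlapping
#' segments, in the one-sided density convention: the rectangle-rule integral
#' of the returned PSD over frequency approximates the signal variance.
#'
#' @param x Numeric signal vector.
#' @param fs Sampling rate (Hz).
#' @param segment_length Segment length N in samples. Defaults to `2 * fs`
#'   (0.5 Hz resolution, putting every band edge on-grid).
#' @param overlap Fractional overlap between consecutive segments in `[0, 1)`.
#' @param window Taper applied to each segment: `"hamming"` (default) or
#'   `"rectangular"`.
#' @param demean Subtract the per-segment mean before tapering? Default FALSE.
#' @return A tibble of class `psd_estimate` with columns `freq` (Hz, from 0 to
#'   fs/2) and `power` (units^2/Hz); attributes `fs` and `n_segments`.
#' @examples
#' t <- (0:999) / 125
#' psd <- welch_psd(sin(2 * pi * 10 * t), fs = 125)
#' sum(psd$power) * diff(psd$freq[1:2]) # ~ 0.5, the power of a unit sinusoid
#' @export
welch_psd <- function(x, fs, segment_length = round(2 * fs), overlap = 0.5,
                      window = c("hamming", "rectangular"), demean = FALSE) {
  window <- match.arg(window)
  x <- as.numeric(x)
  if (all(is.na(x))) stop("signal is all NA", call. = FALSE)
  n <- length(x)
  N <- as.integer(segment_length)
  if (N < 2L) stop("`segment_length` must be at least 2", call. = FALSE)
  if (n < N) stop("signal shorter than one segment", call. = FALSE)
  if (overlap < 0 || overlap >= 1) stop("`overlap` must be in [0, 1)", call. = FALSE)

  w <- if (window == "hamming") {
    0.54 - 0.46 * cos(2 * pi * seq_len(N) / (N + 1))
  } else {
    rep(1, N)
  }
  step <- max(1L, as.integer(round(N * (1 - overlap))))
  starts <- seq.int(1L, n - N + 1L, by = step)
  K <- length(starts)

  half <- floor(N / 2) + 1L
  acc <- numeric(half)
  # per-segment periodogram, normalized by fs * sum(w^2) (density convention)
  for (s in starts) {
    seg <- x[s:(s + N - 1L)]
    if (demean) seg <- seg - mean(seg)
    X <- stats::fft(seg * w)[seq_len(half)]
    acc <- acc + (Re(X)^2 + Im(X)^2)
  }
  pxx <- acc / (K * fs * sum(w^2))
  # fold two-sided density into one-sided (DC and Nyquist not doubled)
  mult <- rep(2, half)
  mult[1L] <- 1
  if (N %% 2L == 0L) mult[half] <- 1
  pxx <- pxx * mult

  out <- tibble::tibble(freq = (seq_len(half) - 1) * fs / N, power = pxx)
  class(out) <- c("psd_estimate", class(out))
  attr(out, "fs") <- fs
  attr(out, "n_segments") <- K
  out
}

#' Short-time spectrogram
#'
#' Gaussian-tapered short-time Fourier transform, magnitude squared, restricted
#' to a frequency band of interest. Time stamps are window centres.
#'
#' @param x Numeric signal vector.
#' @param fs Sampling rate (Hz).
#' @param window_s Analysis window length in seconds (default 10).
#' @param overlap Fractional overlap between windows (default 0.5).
#' @param band_range Length-2 numeric, frequency range (Hz) retained in the
#'   output. Default `c(0.5, 40)`.
#' @param gaussian_alpha Width parameter of the Gaussian taper (default 2.5);
#'   larger values narrow the taper in time.
#' @return A tibble of class `eeg_spectrogram` with columns `time` (s, window
#'   centre), `freq` (Hz) and `power`; attributes `fs` and `window_s`.
#' @export
spectrogram <- function(x, fs, window_s = 10, overlap = 0.5,
                        band_range = c(0.5, 40), gaussian_alpha = 2.5) {
  x <- as.numeric(x)
  L <- as.integer(round(window_s * fs))
  if (L > length(x)) stop("window longer than signal", call. = FALSE)
  if (overlap < 0 || overlap >= 1) stop("`overlap` must be in [0, 1)", call. = FALSE)
  n <- length(x)
  idx <- seq_len(L) - (L + 1) / 2
  w <- exp(-0.5 * (gaussian_alpha * idx / (L / 2))^2)
  step <- max(1L, as.integer(round(L * (1 - overlap))))
  starts <- seq.int(1L, n - L + 1L, by = step)
  half <- floor(L / 2) + 1L
  freqs <- (seq_len(half) - 1) * fs / L
  keep <- freqs >= band_range[1] & freqs <= band_range[2]

  slices <- lapply(starts, function(s) {
    X <- stats::fft(x[s:(s + L - 1L)] * w)[seq_len(half)]
    pw <- (Re(X)^2 + Im(X)^2) / (fs * sum(w^2))
    mult <- rep(2, half)
    mult[1L] <- 1
    if (L %% 2L == 0L) mult[half] <- 1
    tibble::tibble(
      time = (s - 1 + (L - 1) / 2) / fs,
      freq = freqs[keep],
      power = (pw * mult)[keep]
    )
  })
  out <- dplyr::bind_rows(slices)
  class(out) <- c("eeg_spectrogram", class(out))
  attr(out, "fs") <- fs
  attr(out, "window_s") <- window_s
  out
}

#' Integrated band power from a PSD estimate
#'
#' Rectangle-rule integral of the PSD over the half-open band `[lo, hi)`,
#' in density units times Hz (i.e. signal units squared).
#'
#' @param psd A [welch_psd()] result (or any tibble with `freq` and `power`).
#' @param band Either a band name from [eeg_bands()] or a length-2 numeric
#'   `c(lo, hi)` in Hz.
#' @return Non-negative scalar band power.
#' @examples
#' t <- (0:1999) / 125
#' band_power(welch_psd(sin(2 * pi * 10 * t), 125), "alpha") # ~0.5
#' @export
band_power <- function(psd, band) {
  if (is.character(band)) {
    bd <- eeg_bands()
    row <- bd[bd$band == band, ]
    if (nrow(row) != 1L) {
      stop("unknown band `", band, "`; use one of: ",
        paste(bd$band, collapse = ", "),
        call. = FALSE
      )
    }
    band <- c(row$lo, row$hi)
  }
  stopifnot(is.numeric(band), length(band) == 2L, band[1] < band[2])
  df <- diff(psd$freq[1:2])
  sel <- psd$freq >= band[1] & psd$freq < band[2]
  if (!any(sel)) {
    stop("no PSD bins fall inside [", band[1], ", ", band[2],
      ") Hz; frequency grid too coarse",
      call. = FALSE
    )
  }
  sum(psd$power[sel]) * df
}
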
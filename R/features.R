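#' Segment a labelled recording into analysis windows
#'
#' Non-overlapping, contiguous, half-open 10-s windows
#' `[i * window_s, (i + 1) * window_s)` with 0-based indices; a trailing
#' partial window is dropped. Each window carries the fraction of drowsy
#' samples it contains.
#'
#' @param rec A labelled [eeg_recording()].
#' @param window_s Window length in seconds (default 10).
#' @return A tibble with one row per (channel, window): `subject_id`,
#'   `channel`, `window_index`, `start` / `end` (sample indices, 1-based
#'   inclusive) and `label_fraction`.
#' @export
segment_windows <- function(rec, window_s = 10) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!"label" %in% names(rec$data)) {
    stop("recording has no labels; windows cannot be labelled", call. = FALSE)
  }
  L <- as.integer(round(window_s * rec$fs))
  n <- nrow(rec$data)
  n_win <- n %/% L
  if (n_win < 1L) stop("recording shorter than one window", call. = FALSE)
  idx <- seq_len(n_win) - 1L
  frac <- vapply(idx, function(i) {
    mean(rec$data$label[(i * L + 1L):((i + 1L) * L)])
  }, numeric(1))
  tidyr::expand_grid(channel = rec$channels, window_index = idx) |>
    dplyr::mutate(
      subject_id = rec$subject_id,
      start = .data$window_index * L + 1L,
      end = (.data$window_index + 1L) * L,
      label_fraction = frac[.data$window_index + 1L],
      .before = 1L
    ) |>
    dplyr::relocate("subject_id", "channel", "window_index")
}

#' Window label from the drowsy-sample fraction
#'
#' Duration-weighted majority vote: a window is labelled drowsy (1) when the
#' fraction of drowsy samples is at least `threshold`; a tie at exactly the
#' threshold goes to the drowsy (positive) class.
#'
#' @param label_fraction Fraction of drowsy samples in the window, in `[0, 1]`.
#' @param threshold Decision threshold (default 0.5).
#' @return Integer 0/1 (vectorised).
#' @export
assign_window_label <- function(label_fraction, threshold = 0.5) {
  stopifnot(all(label_fraction >= 0 & label_fraction <= 1))
  as.integer(label_fraction >= threshold)
}

#' Band power ratios
#'
#' The four ratio indices of the alert-to-drowsy spectral shift:
#' `R1 = (alpha + theta) / beta`, `R2 = alpha / beta`,
#' `R3 = (alpha + theta) / (alpha + beta)`, `R4 = theta / beta`.
#' `R1 = R2 + R4` holds identically. A zero denominator yields `NA` for the
#' affected ratios and sets `ratio_flag`, never a silent `Inf`.
#'
#' @param p_delta,p_theta,p_alpha,p_beta Non-negative band powers (vectorised).
#' @return A tibble with columns `r1`, `r2`, `r3`, `r4`, `ratio_flag`.
#' @examples
#' compute_bpr(1, 2, 3, 4) # r1 = 1.25, r2 = 0.75, r3 = 5/7, r4 = 0.5
#' @export
compute_bpr <- function(p_delta, p_theta, p_alpha, p_beta) {
  stopifnot(all(p_beta >= 0), all(p_alpha >= 0), all(p_theta >= 0))
  beta_zero <- p_beta == 0
  ab_zero <- (p_alpha + p_beta) == 0
  safe <- function(num, den, bad) ifelse(bad, NA_real_, num / ifelse(bad, 1, den))
  tibble::tibble(
    r1 = safe(p_alpha + p_theta, p_beta, beta_zero),
    r2 = safe(p_alpha, p_beta, beta_zero),
    r3 = safe(p_alpha + p_theta, p_alpha + p_beta, ab_zero),
    r4 = safe(p_theta, p_beta, beta_zero),
    ratio_flag = beta_zero | ab_zero
  )
}

#' Band powers of one windowed segment
#'
#' Within-window Welch PSD (default 2-s Hamming segments, 50% overlap)
#' integrated over the delta, theta, alpha and beta bands.
#'
#' @param samples Numeric vector, one analysis window of a preprocessed
#'   channel.
#' @param fs Sampling rate (Hz).
#' @param segment_length,overlap Welch parameters, see [welch_psd()].
#' @return A named numeric vector `c(p_delta, p_theta, p_alpha, p_beta)`.
#' @export
extract_band_powers <- function(samples, fs, segment_length = round(2 * fs),
                                overlap = 0.5) {
  psd <- welch_psd(samples, fs, segment_length = segment_length, overlap = overlap)
  c(
    p_delta = band_power(psd, "delta"),
    p_theta = band_power(psd, "theta"),
    p_alpha = band_power(psd, "alpha"),
    p_beta = band_power(psd, "beta")
  )
}

#' Windowed spectral feature table for a recording
#'
#' The eight-feature table driving the whole pipeline: per 10-s window and
#' channel, the four band powers and the four band-power ratios, plus the
#' majority-vote window label. Ratios are computed on raw band powers;
#' rescaling, when wanted, is a separate step ([rescale_features()]).
#'
#' @param rec A labelled (and normally preprocessed) [eeg_recording()].
#' @param window_s Window length in seconds (default 10).
#' @param label_threshold Drowsy-fraction threshold for the window label.
#' @param segment_length,overlap Welch parameters for the within-window PSD.
#' @return A feature-table tibble (see [validate_feature_table()]).
#' @examples
#' rec <- generate_session(session_config(duration_s = 60, channels = "F8"), seed = 1)
#' extract_features(preprocess_recording(rec))
#' @export
extract_features <- function(rec, window_s = 10, label_threshold = 0.5,
                             segment_length = round(2 * rec$fs), overlap = 0.5) {
  wins <- segment_windows(rec, window_s)
  pows <- purrr::pmap(
    list(wins$channel, wins$start, wins$end),
    function(ch, s, e) {
      extract_band_powers(rec$data[[ch]][s:e], rec$fs,
        segment_length = segment_length, overlap = overlap
      )
    }
  )
  pows <- dplyr::bind_rows(lapply(pows, as.list))
  out <- dplyr::bind_cols(
    wins[c("subject_id", "channel", "window_index")],
    pows,
    compute_bpr(pows$p_delta, pows$p_theta, pows$p_alpha, pows$p_beta)
  )
  out$label <- assign_window_label(wins$label_fraction, label_threshold)
  out$label_fraction <- wins$label_fraction
  validate_feature_table(out)
  out
}

#' Feature column names of the eight-feature set
#' @return Character vector of the 8 feature columns.
#' @export
feature_names <- function() {
  c("p_delta", "p_theta", "p_alpha", "p_beta", "r1", "r2", "r3", "r4")
}

#' Min-max rescaling of feature columns
#'
#' Linear rescaling of each feature to `[a, b]` (default `[0, 1]`) with the
#' per-feature minimum and maximum learned on a fit scope: by default the
#' whole table, or a subset of rows (e.g. training folds) via `fit_rows`.
#' Values outside the fit scope may leave `[a, b]`; set `clip = TRUE` to clip
#' them. A constant feature maps to `a` with a warning.
#'
#' @param table A feature table (or any data frame).
#' @param features Columns to rescale. Default [feature_names()] intersected
#'   with the table.
#' @param range Output range `c(a, b)`, `a < b`. Default `c(0, 1)`.
#' @param fit_rows Logical or integer row index defining the fit scope;
#'   default all rows.
#' @param clip Clip transformed values into `[a, b]`? Default FALSE.
#' @return The table with the selected columns rescaled.
#' @examples
#' rescale_features(tibble::tibble(p_delta = c(2, 4, 6)), "p_delta")
#' @export
rescale_features <- function(table, features = intersect(feature_names(), names(table)),
                             range = c(0, 1), fit_rows = NULL, clip = FALSE) {
  if (nrow(table) == 0L) stop("empty table", call. = FALSE)
  stopifnot(length(range) == 2L, range[1] < range[2])
  if (is.null(fit_rows)) fit_rows <- seq_len(nrow(table))
  if (length(seq_len(nrow(table))[fit_rows]) == 0L) {
    stop("empty fit scope", call. = FALSE)
  }
  a <- range[1]
  b <- range[2]
  for (col in features) {
    x <- table[[col]]
    fit <- x[fit_rows]
    lo <- min(fit, na.rm = TRUE)
    hi <- max(fit, na.rm = TRUE)
    if (hi == lo) {
      warning("feature `", col, "` is constant on the fit scope; mapped to ", a,
        call. = FALSE
      )
      y <- rep(a, length(x))
      y[is.na(x)] <- NA_real_
    } else {
      y <- a + (x - lo) / (hi - lo) * (b - a)
      if (clip) y <- pmin(pmax(y, a), b)
    }
    table[[col]] <- y
  }
  table
}
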
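#' Multichannel EEG recording
#'
#' A light container for a multichannel EEG time series: a tibble with one
#' `time_s` column, one numeric column per channel (amplitudes in microvolts),
#' and optionally a binary `label` column (1 = drowsy, 0 = alert) on the same
#' sample grid, together with the sampling rate and a subject identifier.
#'
#' @param data A data frame with columns `time_s`, one per channel, and
#'   optionally `label` (integer 0/1, same length as the signals).
#' @param fs Sampling rate in Hz (> 0).
#' @param subject_id Subject identifier string.
#' @return An object of class `eeg_recording`: a list with elements `data`
#'   (tibble), `fs`, `channels` (character vector) and `subject_id`.
#' @examples
#' rec <- eeg_recording(
#'   tibble::tibble(time_s = (0:249) / 125, F8 = rnorm(250)),
#'   fs = 125
#' )
#' rec
#' @export
eeg_recording <- function(data, fs, subject_id = "S01") {
  data <- tibble::as_tibble(data)
  if (!"time_s" %in% names(data)) {
    stop("`data` must contain a `time_s` column", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a single positive number (Hz)", call. = FALSE)
  }
  channels <- setdiff(names(data), c("time_s", "label"))
  if (length(channels) == 0L) {
    stop("recording has no channel columns", call. = FALSE)
  }
  for (ch in channels) {
    if (!is.numeric(data[[ch]])) {
      stop("channel column `", ch, "` is not numeric", call. = FALSE)
    }
  }
  if ("label" %in% names(data)) {
    lab <- data$label
    if (anyNA(lab) || !all(lab %in% c(0L, 1L))) {
      stop("`label` must be 0/1 with no missing values", call. = FALSE)
    }
    data$label <- as.integer(lab)
  }
  structure(
    list(
      data = data,
      fs = fs,
      channels = channels,
      subject_id = as.character(subject_id)
    ),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  dur <- nrow(x$data) / x$fs
  cat(sprintf(
    "<eeg_recording> subject %s: %d channel(s) [%s], %.1f s @ %g Hz%s\n",
    x$subject_id, length(x$channels), paste(x$channels, collapse = ", "),
    dur, x$fs,
    if ("label" %in% names(x$data)) {
      sprintf(", %.1f%% drowsy", 100 * mean(x$data$label))
    } else {
      ", unlabelled"
    }
  ))
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) c(nrow(x$data), length(x$channels))

#' Extract one channel's samples
#'
#' @param rec An [eeg_recording()].
#' @param channel Channel name.
#' @return Numeric vector of samples (microvolts).
#' @export
channel_signal <- function(rec, channel) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!channel %in% rec$channels) {
    stop(
      "unknown channel `", channel, "`; recording has: ",
      paste(rec$channels, collapse = ", "),
      call. = FALSE
    )
  }
  rec$data[[channel]]
}

# Internal: run-length runs of a state vector as (start, end, value) tibble.
state_runs <- function(states) {
  r <- rle(as.integer(states))
  ends <- cumsum(r$lengths)
  tibble::tibble(
    start = c(1L, utils::head(ends, -1L) + 1L),
    end = ends,
    value = r$values
  )
}
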
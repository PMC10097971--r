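#' Write a recording to CSV
#'
#' One column per channel (microvolts) plus `time_s` and, when present,
#' `label`. A comment header line carries the sampling rate and subject id so
#' the file round-trips losslessly through [read_recording()].
#'
#' @param rec An [eeg_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  meta <- sprintf(
    "# drowsEEG recording; fs_hz=%.10g; subject_id=%s",
    rec$fs, rec$subject_id
  )
  writeLines(meta, path)
  readr::write_csv(rec$data, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a recording from CSV or EDF
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"csv"` or `"edf"`.
#' @return An [eeg_recording()]; channel order as stored, amplitudes in
#'   microvolts, labels attached when present.
#' @export
read_recording <- function(path, format = c("auto", "csv", "edf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  if (format == "edf") {
    return(read_recording_edf(path))
  }
  first <- readLines(path, n = 1L)
  fs <- NA_real_
  subject_id <- "S01"
  if (startsWith(first, "#")) {
    m <- regmatches(first, regexec("fs_hz=([0-9.eE+-]+)", first))[[1]]
    if (length(m) == 2L) fs <- as.numeric(m[2])
    m <- regmatches(first, regexec("subject_id=([^;,[:space:]]+)", first))[[1]]
    if (length(m) == 2L) subject_id <- m[2]
  }
  dat <- readr::read_csv(path,
    comment = "#", show_col_types = FALSE,
    progress = FALSE
  )
  if (is.na(fs)) {
    if (!"time_s" %in% names(dat) || nrow(dat) < 2L) {
      stop("missing sampling-rate metadata and no `time_s` column to infer it from",
        call. = FALSE
      )
    }
    fs <- 1 / stats::median(diff(dat$time_s))
  }
  for (col in setdiff(names(dat), "time_s")) {
    if (anyNA(dat[[col]])) {
      stop("column `", col, "` is shorter than the others (missing values)",
        call. = FALSE
      )
    }
  }
  eeg_recording(dat, fs = fs, subject_id = subject_id)
}

# ---- minimal standard 16-bit EDF support ------------------------------------
# Fixed-width ASCII header (256 bytes + 256 per signal), 1-s data records of
# little-endian int16 samples per signal. Labels are stored as an extra
# "Label" signal on the same grid. Covers exactly what the generator writes.

edf_field <- function(x, width) {
  s <- formatC(as.character(x), width = -width)
  substr(s, 1L, width)
}

#' Write a recording as EDF
#'
#' Standard 16-bit EDF with one signal per channel and the binary label (when
#' present) as an extra `Label` signal. Data records are 1 s long, so a
#' trailing partial second is dropped with a warning. Amplitudes are
#' quantized to 16 bits over each channel's observed range.
#'
#' @param rec An [eeg_recording()]; `fs` must be a whole number.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) {
    stop("EDF writer requires an integer sampling rate", call. = FALSE)
  }
  fs <- as.integer(round(fs))
  n <- nrow(rec$data)
  n_rec <- n %/% fs
  if (n_rec < 1L) stop("recording shorter than one 1-s EDF record", call. = FALSE)
  if (n_rec * fs < n) {
    warning("dropping trailing partial second (", n - n_rec * fs, " samples)",
      call. = FALSE
    )
  }
  has_label <- "label" %in% names(rec$data)
  sig_names <- c(rec$channels, if (has_label) "Label")
  ns <- length(sig_names)

  phys_min <- phys_max <- numeric(ns)
  dig <- matrix(0L, nrow = n_rec * fs, ncol = ns)
  for (j in seq_len(ns)) {
    x <- if (has_label && j == ns) {
      as.numeric(rec$data$label[seq_len(n_rec * fs)])
    } else {
      rec$data[[sig_names[j]]][seq_len(n_rec * fs)]
    }
    lo <- min(x)
    hi <- max(x)
    if (hi <= lo) hi <- lo + 1
    phys_min[j] <- lo
    phys_max[j] <- hi
    dig[, j] <- as.integer(round(-32768 + (x - lo) / (hi - lo) * 65535))
  }

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_field("0", 8),
    edf_field(paste("X X X", rec$subject_id), 80),
    edf_field("Startdate X X X X", 80),
    edf_field("01.01.26", 8), edf_field("00.00.00", 8),
    edf_field(256 * (ns + 1), 8),
    edf_field("", 44),
    edf_field(n_rec, 8),
    edf_field(1, 8),
    edf_field(ns, 4)
  )
  per_sig <- function(values, width) {
    paste(vapply(values, edf_field, "", width = width), collapse = "")
  }
  hdr <- paste0(
    hdr,
    per_sig(sig_names, 16),
    per_sig(rep("", ns), 80),
    per_sig(c(rep("uV", ns - has_label), if (has_label) ""), 8),
    per_sig(formatC(phys_min, format = "g", digits = 7), 8),
    per_sig(formatC(phys_max, format = "g", digits = 7), 8),
    per_sig(rep(-32768L, ns), 8),
    per_sig(rep(32767L, ns), 8),
    per_sig(rep("", ns), 80),
    per_sig(rep(fs, ns), 8),
    per_sig(rep("", ns), 32)
  )
  writeChar(hdr, con, eos = NULL)
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1L) * fs + 1L):(r * fs)
    for (j in seq_len(ns)) {
      writeBin(dig[rows, j], con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

read_recording_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8) # version
  patient <- rd(80)
  rd(80)
  rd(8)
  rd(8)
  rd(8) # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1L) stop("not a valid EDF header", call. = FALSE)
  rdv <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- rdv(16)
  rdv(80)
  rdv(8)
  phys_min <- as.numeric(rdv(8))
  phys_max <- as.numeric(rdv(8))
  dig_min <- as.numeric(rdv(8))
  dig_max <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8))
  rdv(32)
  if (length(unique(spr)) != 1L) {
    stop("EDF signals with differing sampling rates are not supported", call. = FALSE)
  }
  fs <- spr[1] / rec_dur
  sig <- matrix(NA_real_, nrow = n_rec * spr[1], ncol = ns)
  for (r in seq_len(n_rec)) {
    for (j in seq_len(ns)) {
      d <- readBin(con, "integer", n = spr[j], size = 2L, signed = TRUE, endian = "little")
      sig[((r - 1L) * spr[1] + 1L):(r * spr[1]), j] <-
        phys_min[j] + (d - dig_min[j]) * (phys_max[j] - phys_min[j]) / (dig_max[j] - dig_min[j])
    }
  }
  n <- nrow(sig)
  dat <- tibble::tibble(time_s = (seq_len(n) - 1) / fs)
  has_label <- any(labels == "Label")
  for (j in seq_len(ns)) {
    if (labels[j] == "Label") {
      dat$label <- as.integer(round(sig[, j]))
    } else {
      dat[[labels[j]]] <- sig[, j]
    }
  }
  subject_id <- utils::tail(strsplit(patient, " +")[[1]], 1L)
  if (length(subject_id) == 0L || subject_id == "X") subject_id <- "S01"
  eeg_recording(dat, fs = fs, subject_id = subject_id)
}

# ---- feature-table IO -------------------------------------------------------

feature_table_schema <- function() {
  c(
    "subject_id", "channel", "window_index",
    "p_delta", "p_theta", "p_alpha", "p_beta",
    "r1", "r2", "r3", "r4", "label"
  )
}

#' Validate a windowed feature table
#'
#' Checks the schema used throughout the pipeline: non-negative, non-missing
#' band powers, binary labels, and strictly increasing window indices within
#' each (subject, channel). Band-power ratios may be `NA` only where
#' `ratio_flag` marks a zero denominator.
#'
#' @param table A feature table (one row per 10-s window and channel).
#' @return `table`, invisibly, if valid; otherwise an error.
#' @export
validate_feature_table <- function(table) {
  missing_cols <- setdiff(feature_table_schema(), names(table))
  if (length(missing_cols) > 0L) {
    stop("feature table lacks column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (nrow(table) == 0L) {
    return(invisible(table))
  }
  for (col in c("p_delta", "p_theta", "p_alpha", "p_beta")) {
    v <- table[[col]]
    if (anyNA(v) || any(!is.finite(v))) {
      stop("band power `", col, "` contains missing/non-finite values", call. = FALSE)
    }
    if (any(v < 0)) stop("band power `", col, "` has negative values", call. = FALSE)
  }
  if (!all(table$label %in% c(0L, 1L))) {
    stop("`label` must be 0 or 1", call. = FALSE)
  }
  flags <- if ("ratio_flag" %in% names(table)) table$ratio_flag else rep(FALSE, nrow(table))
  for (col in c("r1", "r2", "r3", "r4")) {
    if (anyNA(table[[col]][!flags])) {
      stop("ratio `", col, "` is missing on a row not flagged for zero denominator",
        call. = FALSE
      )
    }
  }
  ok <- table |>
    dplyr::group_by(.data$subject_id, .data$channel) |>
    dplyr::summarise(
      sorted = all(diff(.data$window_index) > 0) || dplyr::n() == 1L,
      .groups = "drop"
    )
  if (!all(ok$sorted)) {
    stop("`window_index` must be strictly increasing within (subject, channel)",
      call. = FALSE
    )
  }
  invisible(table)
}

#' Write / read a feature table as CSV
#'
#' Numeric values round-trip losslessly (readr writes the shortest decimal
#' representation that restores the double exactly).
#'
#' @param table A valid feature table (see [validate_feature_table()]).
#' @param path File path.
#' @return `write_feature_table()` returns `path` invisibly;
#'   `read_feature_table()` returns the validated tibble.
#' @export
write_feature_table <- function(table, path) {
  validate_feature_table(table)
  readr::write_csv(table, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(tab) > 0L) {
    tab$label <- as.integer(tab$label)
    tab$window_index <- as.integer(tab$window_index)
  }
  validate_feature_table(tab)
  tab
}
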
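#' Broom-style tidiers and plots
#'
#' `tidy()` methods return per-component tables, `glance()` methods one-row
#' model summaries, and `autoplot()` methods quick ggplot2 views of the main
#' result types.
#'
#' @name drowsEEG-tidiers
NULL

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")

#' Per-fold metrics of a cross-validation result
#'
#' @param x A [cross_validate()] result.
#' @param ... Unused.
#' @return A tibble with one row per fold: accuracy and the confusion counts.
#' @export
tidy.cv_result <- function(x, ...) {
  x$predictions |>
    dplyr::group_by(.data$fold) |>
    dplyr::summarise(
      n = dplyr::n(),
      accuracy = mean(.data$pred == .data$truth),
      tp = sum(.data$truth == 1 & .data$pred == 1),
      fn = sum(.data$truth == 1 & .data$pred == 0),
      fp = sum(.data$truth == 0 & .data$pred == 1),
      tn = sum(.data$truth == 0 & .data$pred == 0),
      .groups = "drop"
    )
}

#' Pooled metrics of a cross-validation result
#'
#' @param x A [cross_validate()] result.
#' @param ... Unused.
#' @return One-row tibble: preset, fold count, the eight confusion-matrix
#'   metrics on the pooled out-of-fold predictions, and AUC.
#' @export
glance.cv_result <- function(x, ...) {
  pr <- x$predictions
  mets <- compute_metrics(confusion(pr$truth, pr$pred))
  auc <- tryCatch(roc_auc(pr$score, pr$truth)$auc, error = function(e) NA_real_)
  dplyr::bind_cols(
    tibble::tibble(preset = x$preset$name, n_folds = x$n_folds, n = nrow(pr)),
    mets[1:8],
    tibble::tibble(auc = auc)
  )
}

#' @export
tidy.coi_result <- function(x, ...) x$tests

#' @export
glance.coi_result <- function(x, ...) {
  tibble::tibble(
    coi = x$coi,
    mean_metric = x$means$mean_metric[1],
    corrected_alpha = x$corrected_alpha,
    all_significant = all(x$tests$significant %in% TRUE)
  )
}

#' @export
tidy.tune_result <- function(x, ...) x$trace

#' @export
glance.tune_result <- function(x, ...) {
  tibble::tibble(
    preset = x$preset$name,
    accuracy = x$accuracy,
    candidates = nrow(x$trace)
  )
}

#' Plot a Welch PSD estimate
#'
#' @param object A [welch_psd()] result.
#' @param dB Plot power in dB/Hz? Default TRUE.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot psd_estimate
#' @export
autoplot.psd_estimate <- function(object, dB = TRUE, ...) {
  df <- tibble::tibble(
    freq = object$freq,
    power = if (dB) 10 * log10(pmax(object$power, 1e-300)) else object$power
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$freq, y = .data$power)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Frequency (Hz)",
      y = if (dB) "PSD (dB/Hz)" else expression("PSD (" * mu * V^2 / Hz * ")")
    ) +
    ggplot2::theme_minimal()
}

#' Plot a spectrogram
#'
#' @param object A [spectrogram()] result.
#' @param dB Colour scale in dB? Default TRUE.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot eeg_spectrogram
#' @export
autoplot.eeg_spectrogram <- function(object, dB = TRUE, ...) {
  df <- tibble::as_tibble(object)
  df$value <- if (dB) 10 * log10(pmax(df$power, 1e-300)) else df$power
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$freq, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = if (dB) "dB" else "power") +
    ggplot2::labs(x = "Time (s)", y = "Frequency (Hz)") +
    ggplot2::theme_minimal()
}

#' Plot a ROC curve
#'
#' @param object A [roc_auc()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot roc_result
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "Fall-out (FPR)", y = "Sensitivity (TPR)",
      title = sprintf("AUC = %.3f", object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Plot fused feature importance
#'
#' Bar chart of the Z-score-fused global predictor importance with the
#' good-candidate band marked.
#'
#' @param object A [gpi_rank()] result.
#' @param candidate_band Band half-width to draw. Default 0.3.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gpi_result
#' @export
autoplot.gpi_result <- function(object, candidate_band = 0.3, ...) {
  df <- tibble::as_tibble(object)
  df$feature <- factor(df$feature, levels = rev(df$feature[order(df$rank)]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gpi, y = .data$feature)) +
    ggplot2::annotate("rect",
      xmin = -candidate_band, xmax = candidate_band,
      ymin = -Inf, ymax = Inf, alpha = 0.1, fill = "steelblue"
    ) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Global predictor importance (mean Z-score)", y = NULL) +
    ggplot2::theme_minimal()
}
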
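#' Binary confusion matrix
#'
#' Counts with drowsy (label 1) as the positive class.
#'
#' @param truth,pred Equal-length 0/1 vectors.
#' @return A list of class `confusion_matrix` with elements `tp`, `fn`, `fp`,
#'   `tn`.
#' @export
confusion <- function(truth, pred) {
  if (length(truth) != length(pred)) stop("length mismatch", call. = FALSE)
  if (!all(truth %in% c(0, 1)) || !all(pred %in% c(0, 1))) {
    stop("labels and predictions must be 0/1", call. = FALSE)
  }
  structure(
    list(
      tp = sum(truth == 1 & pred == 1),
      fn = sum(truth == 1 & pred == 0),
      fp = sum(truth == 0 & pred == 1),
      tn = sum(truth == 0 & pred == 0)
    ),
    class = "confusion_matrix"
  )
}

#' Confusion matrix from printed classification rates
#'
#' Reconstructs the normalized confusion matrix implied by a sensitivity
#' (TPR), specificity (TNR) and positive-class prevalence:
#' `tp = prev * tpr`, `fn = prev * (1 - tpr)`, `tn = (1 - prev) * tnr`,
#' `fp = (1 - prev) * (1 - tnr)`. Every metric formula is scale-free, so
#' these proportions feed [compute_metrics()] directly.
#'
#' @param tpr,tnr,prevalence Rates in `[0, 1]`.
#' @return A `confusion_matrix` of proportions summing to 1.
#' @export
confusion_from_rates <- function(tpr, tnr, prevalence) {
  stopifnot(
    tpr >= 0, tpr <= 1, tnr >= 0, tnr <= 1,
    prevalence > 0, prevalence < 1
  )
  structure(
    list(
      tp = prevalence * tpr,
      fn = prevalence * (1 - tpr),
      fp = (1 - prevalence) * (1 - tnr),
      tn = (1 - prevalence) * tnr
    ),
    class = "confusion_matrix"
  )
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf(
    "<confusion_matrix> TP=%g FN=%g FP=%g TN=%g\n",
    x$tp, x$fn, x$fp, x$tn
  ))
  invisible(x)
}

#' Confusion-matrix performance metrics
#'
#' The eight standard binary metrics evaluated exactly from the counts (or
#' normalized proportions): accuracy, precision (PPV), recall (TPR), F1,
#' specificity (TNR), Matthews correlation coefficient, Cohen's kappa in its
#' two-rater binary form `2(TP*TN - FP*FN) / ((TP+FP)(TN+FP) + (TP+FN)(TN+FN))`,
#' and fall-out (FPR = 1 - TNR). A zero denominator yields `NA` and sets the
#' corresponding `flag_*` column rather than returning an infinity.
#'
#' @param cm A [confusion()] / [confusion_from_rates()] result, or a truth
#'   vector (then `pred` must be given).
#' @param pred Optional predictions when `cm` is a truth vector.
#' @return A one-row tibble with the eight metrics and flags for any
#'   undefined ratios.
#' @examples
#' compute_metrics(confusion_from_rates(0.897, 0.800, 0.571))
#' @export
compute_metrics <- function(cm, pred = NULL) {
  if (!inherits(cm, "confusion_matrix")) cm <- confusion(cm, pred)
  tp <- cm$tp
  tn <- cm$tn
  fp <- cm$fp
  fn <- cm$fn
  n <- tp + tn + fp + fn
  if (n <= 0) stop("empty confusion matrix", call. = FALSE)
  div <- function(num, den) if (den > 0) num / den else NA_real_
  precision <- div(tp, tp + fp)
  recall <- div(tp, tp + fn)
  specificity <- div(tn, fp + tn)
  mcc_den <- sqrt((tp + fp)) * sqrt((tp + fn)) * sqrt((tn + fp)) * sqrt((tn + fn))
  kappa_den <- (tp + fp) * (tn + fp) + (tp + fn) * (tn + fn)
  tibble::tibble(
    accuracy = (tp + tn) / n,
    precision = precision,
    recall = recall,
    f1 = div(2 * tp, 2 * tp + fp + fn),
    specificity = specificity,
    mcc = if (mcc_den > 0) (tp * tn - fp * fn) / mcc_den else NA_real_,
    kappa = if (kappa_den > 0) 2 * (tp * tn - fp * fn) / kappa_den else NA_real_,
    fpr = if (!is.na(specificity)) 1 - specificity else NA_real_,
    flag_precision = is.na(precision),
    flag_recall = is.na(recall),
    flag_specificity = is.na(specificity),
    flag_mcc = !(mcc_den > 0),
    flag_kappa = !(kappa_den > 0)
  )
}

#' ROC curve and AUC
#'
#' Threshold sweep over the unique scores (plus sentinels), reporting
#' (FPR, TPR) points and the trapezoidal area under the curve. Tied scores
#' produce diagonal segments, so the AUC equals the rank statistic
#' P(score_pos > score_neg) + 0.5 P(equal).
#'
#' @param scores Continuous or ordinal classifier scores, larger = more
#'   drowsy.
#' @param truth 0/1 labels; both classes must be present.
#' @return An object of class `roc_result`: tibble of ROC points
#'   (`threshold`, `fpr`, `tpr`) with attribute `auc` (also `$auc` via the
#'   list wrapper).
#' @examples
#' roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc # 0.75
#' @export
roc_auc <- function(scores, truth) {
  stopifnot(length(scores) == length(truth), all(truth %in% c(0, 1)))
  n_pos <- sum(truth == 1)
  n_neg <- sum(truth == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present to compute a ROC curve", call. = FALSE)
  }
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- vapply(thr, function(th) {
    pred <- scores >= th
    c(fpr = sum(pred & truth == 0) / n_neg, tpr = sum(pred & truth == 1) / n_pos)
  }, c(fpr = 0, tpr = 0))
  roc <- tibble::tibble(threshold = thr, fpr = pts["fpr", ], tpr = pts["tpr", ])
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
  structure(list(points = roc, auc = auc), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (%d thresholds)\n", x$auc, nrow(x$points)))
  invisible(x)
}

#' Two-way ANOVA with replication
#'
#' Fixed-effects two-factor analysis of variance with interaction on a
#' balanced replicated design (e.g. accuracy by channel and classifier with
#' subjects as replicates), via `stats::aov`.
#'
#' @param data Data frame in long format.
#' @param value,factor1,factor2 Column names (strings) of the response and
#'   the two factors.
#' @return A tibble with one row per term (`factor1`, `factor2`,
#'   `interaction`): `df`, `sum_sq`, `statistic`, `p_value`. Constant data
#'   yields `NA` statistics with a flag.
#' @export
anova2_replicated <- function(data, value, factor1, factor2) {
  f1 <- factor(data[[factor1]])
  f2 <- factor(data[[factor2]])
  y <- data[[value]]
  counts <- table(f1, f2)
  if (length(unique(as.vector(counts))) != 1L || any(counts < 2)) {
    stop("design must be balanced with at least 2 replicates per cell", call. = FALSE)
  }
  terms <- c(factor1, factor2, "interaction")
  if (stats::var(y) == 0) {
    return(tibble::tibble(
      term = terms, df = NA_real_, sum_sq = 0,
      statistic = NA_real_, p_value = NA_real_, flag_undefined = TRUE
    ))
  }
  fit <- stats::aov(y ~ f1 * f2)
  tab <- summary(fit)[[1]]
  tibble::tibble(
    term = terms,
    df = tab[1:3, "Df"],
    sum_sq = tab[1:3, "Sum Sq"],
    statistic = tab[1:3, "F value"],
    p_value = tab[1:3, "Pr(>F)"],
    flag_undefined = !is.finite(tab[1:3, "F value"])
  )
}

#' Channel-of-interest selection
#'
#' Picks the channel with the highest mean of a per-subject performance
#' metric and validates the choice with paired two-sided t-tests against
#' every other channel under a Bonferroni-corrected threshold `alpha / m`.
#'
#' @param reports Tibble with columns `channel`, `subject_id` and the metric
#'   column; one row per (channel, subject).
#' @param metric Metric column name. Default `"accuracy"`.
#' @param alpha Family-wise significance level. Default 0.05.
#' @param m Number of hypotheses for the Bonferroni correction. Default 5
#'   (the winner against the five other montage channels).
#' @return A list of class `coi_result`: `coi` (winning channel),
#'   `corrected_alpha`, `means` and `tests` tibbles.
#' @export
select_coi <- function(reports, metric = "accuracy", alpha = 0.05, m = 5) {
  stopifnot(all(c("channel", "subject_id", metric) %in% names(reports)))
  means <- reports |>
    dplyr::group_by(.data$channel) |>
    dplyr::summarise(mean_metric = mean(.data[[metric]]), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$mean_metric))
  if (nrow(means) < 2L) stop("need at least 2 channels", call. = FALSE)
  winner <- means$channel[1]
  corrected <- alpha / m
  wide <- reports |>
    dplyr::select("channel", "subject_id", dplyr::all_of(metric)) |>
    tidyr::pivot_wider(names_from = "channel", values_from = dplyr::all_of(metric)) |>
    dplyr::arrange(.data$subject_id)
  others <- setdiff(means$channel, winner)
  n_subj <- nrow(wide)
  tests <- purrr::map_dfr(others, function(ch) {
    if (n_subj < 2L) {
      return(tibble::tibble(
        channel = ch, mean_diff = mean(wide[[winner]] - wide[[ch]]),
        statistic = NA_real_, p_value = NA_real_, significant = NA
      ))
    }
    d <- wide[[winner]] - wide[[ch]]
    if (stats::sd(d) == 0) {
      return(tibble::tibble(
        channel = ch, mean_diff = mean(d),
        statistic = NA_real_, p_value = 1, significant = FALSE
      ))
    }
    tt <- stats::t.test(wide[[winner]], wide[[ch]], paired = TRUE)
    tibble::tibble(
      channel = ch, mean_diff = mean(d),
      statistic = unname(tt$statistic), p_value = tt$p.value,
      significant = tt$p.value < corrected
    )
  })
  if (n_subj < 2L) {
    warning("fewer than 2 subjects: paired tests skipped", call. = FALSE)
  }
  structure(
    list(
      coi = winner, corrected_alpha = corrected,
      metric = metric, means = means, tests = tests
    ),
    class = "coi_result"
  )
}

#' @export
print.coi_result <- function(x, ...) {
  cat(sprintf(
    "<coi_result> channel of interest: %s (mean %s %.3f); %d paired tests at alpha %.4g\n",
    x$coi, x$metric, x$means$mean_metric[1], nrow(x$tests), x$corrected_alpha
  ))
  invisible(x)
}
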
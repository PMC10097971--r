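#' Feature tables for a set of sessions
#'
#' Preprocesses each recording with the filter cascade and extracts the
#' windowed eight-feature table, binding all subjects into one table.
#'
#' @param recordings A list of labelled [eeg_recording()] objects (one per
#'   subject/session).
#' @param spec A [filter_spec()] for preprocessing, or `NULL` to skip it.
#' @param ... Passed to [extract_features()].
#' @return One combined feature table.
#' @export
sessions_to_features <- function(recordings, spec = filter_spec(), ...) {
  if (inherits(recordings, "eeg_recording")) recordings <- list(recordings)
  purrr::map_dfr(recordings, function(rec) {
    if (!is.null(spec)) rec <- preprocess_recording(rec, spec)
    extract_features(rec, ...)
  })
}

#' Per-channel, per-subject cross-validated accuracy
#'
#' Runs stratified cross-validation independently on every (channel,
#' subject) slice of a feature table and reports the pooled out-of-fold
#' accuracy of each slice — the paired observations used by [select_coi()].
#'
#' @param table A combined feature table (multiple channels and subjects).
#' @param preset A [classifier_preset()] or name. Default `"bagged_trees"`.
#' @param n_folds CV folds (default 10; reduced automatically on small
#'   slices).
#' @param seed Integer seed.
#' @param features Feature columns used for classification.
#' @return A tibble with `channel`, `subject_id`, `accuracy`.
#' @export
channel_subject_accuracy <- function(table, preset = "bagged_trees",
                                     n_folds = 10, seed = NULL,
                                     features = intersect(feature_names(), names(table))) {
  slices <- dplyr::group_split(dplyr::group_by(table, .data$channel, .data$subject_id))
  purrr::map_dfr(slices, function(sl) {
    acc <- tryCatch(
      {
        cv <- suppressWarnings(cross_validate(sl, preset,
          n_folds = n_folds,
          seed = seed, features = features
        ))
        mean(cv$predictions$pred == cv$predictions$truth)
      },
      error = function(e) NA_real_
    )
    tibble::tibble(
      channel = sl$channel[1], subject_id = sl$subject_id[1],
      accuracy = acc
    )
  })
}

#' End-to-end drowsiness pipeline on synthetic sessions
#'
#' Generates labelled multichannel sessions for several synthetic subjects,
#' preprocesses them, extracts features, ranks the features on the
#' designated channel's pooled table, evaluates per-channel per-subject
#' classification, and selects the channel of interest.
#'
#' @param n_subjects Number of synthetic subjects. Default 12.
#' @param config A [session_config()] template; `subject_id` is overridden
#'   per subject.
#' @param preset Classifier preset for channel evaluation.
#' @param n_folds CV folds.
#' @param seed Master seed; all per-subject generation and CV seeds derive
#'   from it.
#' @return A list: `features` (combined table), `ranking` (the
#'   [rank_features()] output for the designated channel), `channel_accuracy`
#'   (per channel and subject) and `coi` (a [select_coi()] result).
#' @export
run_pipeline <- function(n_subjects = 12, config = session_config(),
                         preset = "bagged_trees", n_folds = 10, seed = 1) {
  recs <- lapply(seq_len(n_subjects), function(i) {
    cfg <- config
    cfg$subject_id <- sprintf("S%02d", i)
    generate_session(cfg, seed = (as.integer(seed) + 7919L * i) %% 2147483629L)
  })
  feats <- sessions_to_features(recs)
  coi_table <- dplyr::filter(feats, .data$channel == config$coi)
  coi_table <- rescale_features(coi_table)
  ranking <- rank_features(coi_table)
  acc <- channel_subject_accuracy(feats,
    preset = preset, n_folds = n_folds,
    seed = (as.integer(seed) + 13L) %% 2147483629L
  )
  coi <- select_coi(acc)
  list(
    features = feats, ranking = ranking,
    channel_accuracy = acc, coi = coi
  )
}

#' Seed-swept parameter-recovery study
#'
#' Repeats the end-to-end pipeline over several master seeds and summarizes
#' how often the designated channel of interest is recovered and where the
#' band powers land in the fused feature ranking.
#'
#' @param n_seeds Number of independent repetitions. Default 10.
#' @param n_subjects Synthetic subjects per repetition. Default 12.
#' @param config A [session_config()] template.
#' @param eval_preset Classifier preset used for the per-channel,
#'   per-subject accuracy that drives channel selection. Default
#'   `"medium_tree"`, a fast evaluator whose channel ordering tracks the
#'   ensemble's.
#' @param seed Base seed; repetition `r` uses `seed + 1000 * (r - 1)`.
#' @return A list: `per_seed` (tibble with `seed`, `coi`, `coi_correct`,
#'   `powers_in_top4`), `gpi_mean` (per-feature fused importance averaged
#'   over repetitions, ranked) and `coi_features` (the pooled, rescaled
#'   feature table of the designated channel from the first repetition, for
#'   downstream tuning).
#' @export
recovery_study <- function(n_seeds = 10, n_subjects = 12,
                           config = session_config(duration_s = 600),
                           eval_preset = "medium_tree", seed = 1) {
  power_feats <- c("p_delta", "p_theta", "p_alpha", "p_beta")
  per_seed <- vector("list", n_seeds)
  gpis <- vector("list", n_seeds)
  coi_features <- NULL
  for (r in seq_len(n_seeds)) {
    seed_r <- (as.integer(seed) + 1000L * (r - 1L)) %% 2147483629L
    res <- suppressWarnings(run_pipeline(
      n_subjects = n_subjects, config = config,
      preset = eval_preset, seed = seed_r
    ))
    gpi <- res$ranking$gpi
    if (r == 1L) {
      coi_features <- rescale_features(
        dplyr::filter(res$features, .data$channel == config$coi)
      )
    }
    gpis[[r]] <- tibble::tibble(seed = seed_r, feature = gpi$feature, gpi = gpi$gpi)
    per_seed[[r]] <- tibble::tibble(
      seed = seed_r,
      coi = res$coi$coi,
      coi_correct = res$coi$coi == config$coi,
      powers_in_top4 = sum(gpi$feature[1:4] %in% power_feats)
    )
  }
  gpi_mean <- dplyr::bind_rows(gpis) |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(gpi = mean(.data$gpi), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$gpi))
  gpi_mean$rank <- seq_len(nrow(gpi_mean))
  list(
    per_seed = dplyr::bind_rows(per_seed),
    gpi_mean = gpi_mean,
    coi_features = coi_features
  )
}

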
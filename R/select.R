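# Equal-frequency discretization; variables with few distinct values are kept
# as-is (so a binary label stays binary).
discretize_ef <- function(x, n_bins = 10) {
  ux <- unique(x)
  if (length(ux) <= n_bins) {
    return(match(x, sort(ux)))
  }
  breaks <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
    names = FALSE, type = 7
  ))
  if (length(breaks) < 3L) {
    return(rep(1L, length(x)))
  }
  as.integer(cut(x, breaks = breaks, include.lowest = TRUE))
}

#' Plug-in mutual information between two variables
#'
#' Entropy-based mutual information (in nats) on the joint histogram after
#' equal-frequency discretization of continuous variables into `n_bins`
#' cells. Discrete variables (at most `n_bins` distinct values, e.g. a binary
#' label) are used as-is. `MI(x, x)` equals the entropy of the discretized
#' variable; a constant variable has MI 0 with anything.
#'
#' @param x,y Numeric vectors of equal length (>= 2 observations).
#' @param n_bins Number of discretization bins (>= 2). Default 10.
#' @return Non-negative scalar, nats.
#' @examples
#' mutual_information(1:100, 1:100) # ~ log(10)
#' @export
mutual_information <- function(x, y, n_bins = 10) {
  stopifnot(length(x) == length(y), length(x) >= 2L, n_bins >= 2L)
  dx <- discretize_ef(x, n_bins)
  dy <- discretize_ef(y, n_bins)
  joint <- table(dx, dy) / length(x)
  px <- rowSums(joint)
  py <- colSums(joint)
  mi <- 0
  for (i in seq_along(px)) {
    for (j in seq_along(py)) {
      p <- joint[i, j]
      if (p > 0) mi <- mi + p * log(p / (px[i] * py[j]))
    }
  }
  max(0, mi)
}

new_feature_ranking <- function(feature, score, method, extra = NULL) {
  out <- tibble::tibble(feature = feature, score = score, method = method)
  if (!is.null(extra)) out <- dplyr::bind_cols(out, extra)
  out <- out[order(-out$score), ]
  out$rank <- seq_len(nrow(out))
  class(out) <- c("feature_ranking", class(out))
  out
}

#' Minimum-redundancy maximum-relevance feature ranking
#'
#' Greedy forward MRMR: the first pick maximizes relevance `I(p, y)`; each
#' subsequent pick maximizes the quotient of relevance to mean mutual
#' information with the already-selected features (redundancy), the reported
#' score being the selection-time quotient.
#'
#' @param table Feature table with a binary `label` column.
#' @param features Feature columns to rank. Default [feature_names()]
#'   intersected with the table.
#' @param label_col Name of the label column. Default `"label"`.
#' @param n_bins Discretization bins for the mutual-information estimates.
#' @param eps Guard added to the redundancy denominator. Default 1e-12.
#' @return A `feature_ranking` tibble: `feature`, `score`, `method`, `rank`.
#' @export
mrmr_rank <- function(table, features = intersect(feature_names(), names(table)),
                      label_col = "label", n_bins = 10, eps = 1e-12) {
  y <- table[[label_col]]
  X <- as.data.frame(table[features])
  p <- length(features)
  relevance <- vapply(X, mutual_information, numeric(1), y = y, n_bins = n_bins)
  if (p == 1L) {
    return(new_feature_ranking(features, unname(relevance), "mrmr"))
  }
  # pairwise MI cache, filled lazily
  mi_pair <- matrix(NA_real_, p, p)
  pair <- function(i, j) {
    if (is.na(mi_pair[i, j])) {
      mi_pair[i, j] <<- mi_pair[j, i] <<- mutual_information(X[[i]], X[[j]], n_bins = n_bins)
    }
    mi_pair[i, j]
  }
  selected <- integer(0)
  scores <- numeric(p)
  remaining <- seq_len(p)
  first <- remaining[which.max(relevance)]
  scores[first] <- relevance[first]
  selected <- first
  remaining <- setdiff(remaining, first)
  while (length(remaining) > 0L) {
    quot <- vapply(remaining, function(i) {
      red <- mean(vapply(selected, function(j) pair(i, j), numeric(1)))
      relevance[i] / (red + eps)
    }, numeric(1))
    pick <- remaining[which.max(quot)]
    scores[pick] <- max(quot)
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
  }
  # scores are selection-time quotients; enforce the greedy order in the rank
  out <- tibble::tibble(
    feature = features[selected],
    score = scores[selected],
    method = "mrmr",
    rank = seq_along(selected)
  )
  class(out) <- c("feature_ranking", class(out))
  out
}

#' Chi-square feature importance
#'
#' Per feature: equal-frequency discretization into `n_bins` cells, a
#' bins-by-2 contingency table against the binary label, the chi-square
#' statistic over observed vs expected counts, and a p-value with degrees of
#' freedom `(bins_used - 1) * (classes - 1)` (empty bins are merged first).
#' The importance score is `-log(p)`; features with `p < alpha` are marked
#' significant.
#'
#' @inheritParams mrmr_rank
#' @param alpha Significance level. Default 0.05.
#' @return A `feature_ranking` tibble with extra columns `statistic`, `df`,
#'   `p_value`, `significant`.
#' @export
chi2_rank <- function(table, features = intersect(feature_names(), names(table)),
                      label_col = "label", n_bins = 10, alpha = 0.05) {
  y <- table[[label_col]]
  if (length(unique(y)) < 2L) stop("both classes must be present", call. = FALSE)
  stats_list <- lapply(features, function(f) chi2_test(table[[f]], y, n_bins))
  res <- dplyr::bind_rows(stats_list)
  new_feature_ranking(
    features, -log(res$p_value), "chi2",
    extra = tibble::tibble(
      statistic = res$statistic, df = res$df,
      p_value = res$p_value, significant = res$p_value < alpha
    )
  )
}

chi2_test <- function(x, y, n_bins = 10) {
  bins <- discretize_ef(x, n_bins)
  O <- table(bins, y)
  O <- O[rowSums(O) > 0, , drop = FALSE] # merge (drop) empty predictor bins
  n <- sum(O)
  E <- outer(rowSums(O), colSums(O)) / n
  stat <- sum((O - E)^2 / E)
  df <- (nrow(O) - 1L) * (ncol(O) - 1L)
  if (df < 1L) {
    return(tibble::tibble(statistic = 0, df = 0L, p_value = 1))
  }
  tibble::tibble(
    statistic = stat, df = df,
    p_value = stats::pchisq(stat, df, lower.tail = FALSE)
  )
}

#' ReliefF feature weighting
#'
#' Instance-based feature weights: for each observation, the `k` nearest
#' hits (same class) and `k` nearest misses per other class — by Manhattan
#' (L1) distance on range-normalized features — pull the weight of each
#' feature down by the mean normalized hit difference and up by the
#' prior-weighted mean miss difference, accumulated over all `t`
#' observations and divided by `k * t`. With two classes the prior weighting
#' `P_n / (1 - P_p)` equals 1. Weights lie in `[-1, 1]`.
#'
#' @inheritParams mrmr_rank
#' @param k Number of nearest neighbours per class. Reduced with a warning
#'   when a class has fewer than `k + 1` members. Default 10.
#' @param t Number of observations to process; default (`NULL`) all of them.
#'   A value below `n` triggers seeded random subsampling.
#' @param seed Seed for the subsample when `t < n`.
#' @return A `feature_ranking` tibble (`score` = ReliefF weight).
#' @export
relieff_rank <- function(table, features = intersect(feature_names(), names(table)),
                         label_col = "label", k = 10, t = NULL, seed = NULL) {
  y <- as.integer(table[[label_col]])
  X <- as.matrix(table[features])
  n <- nrow(X)
  classes <- sort(unique(y))
  counts <- table(factor(y, levels = classes))
  k_use <- min(k, min(counts) - 1L)
  if (k_use < k) {
    warning("k reduced to ", k_use, ": smallest class has ", min(counts),
      " members",
      call. = FALSE
    )
  }
  if (k_use < 1L) stop("each class needs at least 2 members", call. = FALSE)
  rng <- apply(X, 2, function(col) max(col) - min(col))
  rng[rng == 0] <- 1 # constant features contribute zero differences anyway
  Xn <- sweep(X, 2, rng, "/")
  priors <- as.numeric(counts) / n

  rows <- if (is.null(t) || t >= n) {
    seq_len(n)
  } else {
    if (is.null(seed)) {
      sample(n, t)
    } else {
      withr::with_seed(seed, sample(n, t))
    }
  }
  t_eff <- length(rows)
  D <- as.matrix(stats::dist(Xn, method = "manhattan"))
  W <- numeric(length(features))
  for (r in rows) {
    p_cls <- y[r]
    for (cl in classes) {
      idx <- which(y == cl)
      idx <- idx[idx != r]
      nb <- idx[order(D[r, idx])[seq_len(k_use)]]
      diffs <- colSums(abs(Xn[nb, , drop = FALSE] -
        matrix(Xn[r, ], nrow = length(nb), ncol = ncol(Xn), byrow = TRUE)))
      if (cl == p_cls) {
        W <- W - diffs / (k_use * t_eff)
      } else {
        w_prior <- priors[match(cl, classes)] / (1 - priors[match(p_cls, classes)])
        W <- W + w_prior * diffs / (k_use * t_eff)
      }
    }
  }
  new_feature_ranking(features, unname(W), "relieff")
}

#' Z-score fusion of feature rankings (global predictor importance)
#'
#' Standardizes each method's importance scores across features to zero mean
#' and unit standard deviation and averages the Z-scores across methods.
#' Features whose fused score lies within 0.3 standard deviations of zero
#' are reported as good candidates for the important set.
#'
#' @param rankings A list of `feature_ranking` tibbles (normally MRMR,
#'   chi-square and ReliefF) over the same feature set.
#' @param candidate_band Half-width of the good-candidate band around zero,
#'   in fused-score standard deviations. Default 0.3.
#' @param sd_type `"sample"` (n - 1 denominator, the convention of common
#'   statistics software, default) or `"population"` (n denominator).
#' @return A tibble of class `gpi_result`: `feature`, one `z_<method>` column
#'   per method, `gpi`, `rank`, `good_candidate`.
#' @export
gpi_rank <- function(rankings, candidate_band = 0.3,
                     sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  stopifnot(length(rankings) >= 1L)
  feats <- sort(rankings[[1]]$feature)
  zmat <- sapply(rankings, function(rk) {
    if (!setequal(rk$feature, feats)) {
      stop("rankings cover different feature sets", call. = FALSE)
    }
    x <- rk$score[match(feats, rk$feature)]
    sd_pop <- if (sd_type == "population") {
      sqrt(mean((x - mean(x))^2))
    } else {
      stats::sd(x)
    }
    if (sd_pop == 0) {
      warning("method `", rk$method[1], "` has zero score variance; Z set to 0",
        call. = FALSE
      )
      rep(0, length(x))
    } else {
      (x - mean(x)) / sd_pop
    }
  })
  zmat <- matrix(zmat, nrow = length(feats))
  colnames(zmat) <- vapply(rankings, function(rk) rk$method[1], "")
  gpi <- rowMeans(zmat)
  out <- tibble::as_tibble(as.data.frame(zmat)) |>
    stats::setNames(paste0("z_", colnames(zmat)))
  out <- dplyr::bind_cols(tibble::tibble(feature = feats), out)
  out$gpi <- gpi
  out <- out[order(-out$gpi), ]
  out$rank <- seq_len(nrow(out))
  out$good_candidate <- abs(out$gpi) <= candidate_band
  class(out) <- c("gpi_result", class(out))
  out
}

#' Run the full three-method ranking ensemble
#'
#' Convenience wrapper: MRMR, chi-square and ReliefF rankings on one feature
#' table, fused by [gpi_rank()].
#'
#' @inheritParams mrmr_rank
#' @param k ReliefF neighbour count. Default 10.
#' @return A list with elements `mrmr`, `chi2`, `relieff` (each a
#'   `feature_ranking`) and `gpi` (a `gpi_result`).
#' @export
rank_features <- function(table, features = intersect(feature_names(), names(table)),
                          label_col = "label", n_bins = 10, k = 10) {
  rks <- list(
    mrmr = mrmr_rank(table, features, label_col, n_bins = n_bins),
    chi2 = chi2_rank(table, features, label_col, n_bins = n_bins),
    relieff = relieff_rank(table, features, label_col, k = k)
  )
  c(rks, list(gpi = gpi_rank(rks)))
}
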
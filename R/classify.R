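#' Classifier preset
#'
#' A named configuration from the closed preset catalogue
#' ([classifier_presets()]): family, variant and pinned hyperparameters.
#'
#' @param name Preset name, e.g. `"bagged_trees"` or `"fine_gaussian_svm"`.
#' @param ... Hyperparameter overrides for the chosen preset.
#' @return A list of class `classifier_preset`.
#' @export
classifier_preset <- function(name, ...) {
  cat <- preset_catalogue()
  if (!name %in% names(cat)) {
    stop("unknown preset `", name, "`; see classifier_presets()", call. = FALSE)
  }
  preset <- cat[[name]]
  dots <- list(...)
  for (nm in names(dots)) preset$params[[nm]] <- dots[[nm]]
  preset$name <- name
  structure(preset, class = "classifier_preset")
}

preset_catalogue <- function() {
  tree <- function(splits) list(family = "tree", params = list(max_splits = splits))
  knn <- function(k, metric = "euclidean", weight = "equal") {
    list(family = "knn", params = list(k = k, metric = metric, weight = weight))
  }
  svm <- function(scale_factor) {
    # kernel scale = scale_factor * sqrt(P); box constraint C = 1
    list(family = "svm", params = list(scale_factor = scale_factor, cost = 1))
  }
  ens <- function(method, n_learners = 30, learn_rate = 0.1, max_splits = 20,
                  subspace_dim = 4) {
    list(family = "ensemble", params = list(
      method = method, n_learners = n_learners, learn_rate = learn_rate,
      max_splits = max_splits, subspace_dim = subspace_dim
    ))
  }
  list(
    fine_tree = tree(100), medium_tree = tree(20), coarse_tree = tree(4),
    lda = list(family = "discriminant", params = list(type = "linear")),
    qda = list(family = "discriminant", params = list(type = "quadratic")),
    logistic = list(family = "logistic", params = list()),
    gaussian_nb = list(family = "naive_bayes", params = list(kernel = FALSE)),
    kernel_nb = list(family = "naive_bayes", params = list(kernel = TRUE)),
    fine_gaussian_svm = svm(1 / 4),
    medium_gaussian_svm = svm(1),
    coarse_gaussian_svm = svm(4),
    fine_knn = knn(1), medium_knn = knn(10), coarse_knn = knn(100),
    cosine_knn = knn(10, metric = "cosine"),
    cubic_knn = knn(10, metric = "minkowski3"),
    weighted_knn = knn(10, weight = "squared_inverse"),
    bagged_trees = ens("bag", max_splits = Inf),
    boosted_trees = ens("adaboost"),
    rusboosted_trees = ens("rusboost"),
    subspace_discriminant = ens("subspace_discriminant"),
    subspace_knn = ens("subspace_knn")
  )
}

#' Preset catalogue overview
#' @return A tibble listing every preset name and family.
#' @export
classifier_presets <- function() {
  cat <- preset_catalogue()
  tibble::tibble(
    preset = names(cat),
    family = vapply(cat, function(p) p$family, "")
  )
}

#' Gaussian SVM kernel scales for a feature count
#'
#' The fine / medium / coarse kernel scales `sqrt(P)/4`, `sqrt(P)` and
#' `4*sqrt(P)` for `P` features (0.71, 2.8 and 11 at two significant figures
#' when `P = 8`).
#'
#' @param p Number of features.
#' @return Named numeric vector `c(fine, medium, coarse)`.
#' @export
svm_kernel_scales <- function(p) {
  c(fine = sqrt(p) / 4, medium = sqrt(p), coarse = 4 * sqrt(p))
}

#' Logistic (sigmoid) class probability
#'
#' Probability of the positive class from an affine score:
#' `p(x) = exp(a0 + a'x) / (1 + exp(a0 + a'x))`.
#'
#' @param coefficients Numeric vector `c(a0, a1, ..., aP)` (intercept first);
#'   length must be one more than the feature count.
#' @param x A numeric vector of one observation's features, or a matrix/data
#'   frame with observations in rows.
#' @return Probability (vector) in `(0, 1)`.
#' @examples
#' logistic_predict(c(log(3), 0), 5) # 0.75
#' @export
logistic_predict <- function(coefficients, x) {
  if (is.null(dim(x))) x <- matrix(as.numeric(x), nrow = 1)
  x <- as.matrix(x)
  if (length(coefficients) != ncol(x) + 1L) {
    stop("need ", ncol(x) + 1L, " coefficients (intercept + one per feature)",
      call. = FALSE
    )
  }
  eta <- coefficients[1] + drop(x %*% coefficients[-1])
  stats::plogis(eta)
}

# ---- fit / predict per family ----------------------------------------------

tree_depth <- function(max_splits, n_train) {
  splits <- min(max_splits, n_train - 1)
  max(1L, min(30L, as.integer(ceiling(log2(splits + 1)))))
}

fit_rpart <- function(X, y, max_splits, weights = NULL) {
  df <- as.data.frame(X)
  df$.y <- factor(y, levels = c(0L, 1L))
  rpart::rpart(.y ~ .,
    data = df, weights = weights, method = "class",
    control = rpart::rpart.control(
      cp = 0, minsplit = 2, minbucket = 1, xval = 0,
      maxdepth = tree_depth(max_splits, nrow(df))
    )
  )
}

predict_rpart_prob <- function(fit, X) {
  p <- predict(fit, as.data.frame(X), type = "prob")
  if (is.null(dim(p))) p <- matrix(p, ncol = 2)
  if (!"1" %in% colnames(p)) {
    return(rep(0, nrow(X)))
  }
  p[, "1"]
}

knn_distance <- function(train, test, metric) {
  switch(metric,
    euclidean = {
      cross <- test %*% t(train)
      d2 <- outer(rowSums(test^2), rowSums(train^2), "+") - 2 * cross
      sqrt(pmax(d2, 0))
    },
    cosine = {
      nt <- sqrt(rowSums(test^2))
      nr <- sqrt(rowSums(train^2))
      nt[nt == 0] <- 1
      nr[nr == 0] <- 1
      1 - (test %*% t(train)) / outer(nt, nr)
    },
    minkowski3 = {
      out <- matrix(0, nrow(test), nrow(train))
      for (j in seq_len(ncol(train))) {
        out <- out + abs(outer(test[, j], train[, j], "-"))^3
      }
      out^(1 / 3)
    },
    stop("unknown kNN metric `", metric, "`", call. = FALSE)
  )
}

knn_score <- function(train, y, test, k, metric, weight) {
  k <- min(k, nrow(train))
  D <- knn_distance(train, test, metric) # test rows x train columns
  vapply(seq_len(nrow(test)), function(i) {
    ord <- order(D[i, ])[seq_len(k)]
    w <- switch(weight,
      equal = rep(1, k),
      squared_inverse = 1 / (D[i, ord]^2 + 1e-12)
    )
    sum(w * (y[ord] == 1L)) / sum(w)
  }, numeric(1))
}

# LDA/QDA on degenerate inputs (a feature constant within a class) gets a
# vanishing jitter so the covariance estimate is full rank.
safe_da <- function(X, y, quadratic = FALSE) {
  grp <- factor(y, levels = c(0L, 1L))
  fit_fun <- if (quadratic) MASS::qda else MASS::lda
  tryCatch(fit_fun(X, grouping = grp), error = function(e) {
    scale <- pmax(apply(X, 2, function(c) diff(range(c))), 1)
    Xj <- X + matrix(stats::rnorm(length(X), sd = 1e-3), nrow(X)) %*% diag(scale, ncol(X))
    tryCatch(fit_fun(Xj, grouping = grp), error = function(e2) {
      if (quadratic) {
        warning("QDA failed (", conditionMessage(e2), "); falling back to LDA",
          call. = FALSE
        )
        safe_da(X, y, quadratic = FALSE)
      } else {
        stop(e2)
      }
    })
  })
}

fit_model <- function(X, y, preset) {
  X <- as.matrix(X)
  p <- preset$params
  fit <- switch(preset$family,
    tree = list(model = fit_rpart(X, y, p$max_splits)),
    discriminant = list(model = safe_da(X, y, quadratic = p$type == "quadratic")),
    logistic = {
      fit <- suppressWarnings(
        stats::glm.fit(cbind(1, X), y, family = stats::binomial())
      )
      list(coef = ifelse(is.na(fit$coefficients), 0, fit$coefficients))
    },
    naive_bayes = {
      if (p$kernel) {
        list(kde = kernel_nb_fit(X, y))
      } else {
        list(model = e1071::naiveBayes(as.data.frame(X), factor(y, levels = c(0L, 1L))))
      }
    },
    svm = {
      ks <- p$scale_factor * sqrt(ncol(X))
      list(model = e1071::svm(X, factor(y, levels = c(0L, 1L)),
        kernel = "radial", gamma = 1 / (2 * ks^2), cost = p$cost, scale = FALSE
      ))
    },
    knn = list(train = X, y = y),
    ensemble = fit_ensemble(X, y, p),
    stop("unknown classifier family `", preset$family, "`", call. = FALSE)
  )
  fit$preset <- preset
  fit
}

predict_model <- function(fit, X) {
  X <- as.matrix(X)
  preset <- fit$preset
  p <- preset$params
  score <- switch(preset$family,
    tree = predict_rpart_prob(fit$model, X),
    discriminant = {
      pr <- predict(fit$model, X)$posterior
      if ("1" %in% colnames(pr)) pr[, "1"] else rep(0, nrow(X))
    },
    logistic = logistic_predict(fit$coef, X),
    naive_bayes = {
      if (p$kernel) {
        kernel_nb_predict(fit$kde, X)
      } else {
        predict(fit$model, as.data.frame(X), type = "raw")[, "1"]
      }
    },
    svm = {
      dv_attr <- attr(predict(fit$model, X, decision.values = TRUE), "decision.values")
      dv <- drop(dv_attr)
      # e1071 names the decision value "a/b": positive means class a
      if (startsWith(colnames(dv_attr)[1], "0/")) dv <- -dv
      stats::plogis(dv)
    },
    knn = knn_score(fit$train, fit$y, X, p$k, p$metric, p$weight),
    ensemble = predict_ensemble(fit, X)
  )
  list(class = as.integer(score >= 0.5), score = as.numeric(score))
}

# Kernel naive Bayes: per class and feature, a Gaussian-kernel density
# estimate; posterior from log-likelihood sums plus log priors.
kernel_nb_fit <- function(X, y) {
  classes <- c(0L, 1L)
  dens <- lapply(classes, function(cl) {
    lapply(seq_len(ncol(X)), function(j) {
      x <- X[y == cl, j]
      if (length(unique(x)) < 2L) {
        list(const = TRUE, value = x[1])
      } else {
        d <- stats::density(x, n = 512, cut = 3)
        list(const = FALSE, fx = stats::approxfun(d$x, d$y, yleft = 0, yright = 0))
      }
    })
  })
  list(dens = dens, priors = c(mean(y == 0L), mean(y == 1L)))
}

kernel_nb_predict <- function(kde, X) {
  loglik <- sapply(1:2, function(ci) {
    ll <- rep(log(kde$priors[ci] + 1e-300), nrow(X))
    for (j in seq_len(ncol(X))) {
      d <- kde$dens[[ci]][[j]]
      fx <- if (d$const) {
        ifelse(abs(X[, j] - d$value) < 1e-12, 1, 1e-12)
      } else {
        pmax(d$fx(X[, j]), 1e-12)
      }
      ll <- ll + log(fx)
    }
    ll
  })
  if (is.null(dim(loglik))) loglik <- matrix(loglik, ncol = 2)
  m <- pmax(loglik[, 1], loglik[, 2])
  exp(loglik[, 2] - m) / (exp(loglik[, 1] - m) + exp(loglik[, 2] - m))
}

# ---- ensembles --------------------------------------------------------------

fit_ensemble <- function(X, y, p) {
  n <- nrow(X)
  members <- vector("list", p$n_learners)
  alphas <- rep(1, p$n_learners)
  subspaces <- vector("list", p$n_learners)
  method <- p$method

  if (method %in% c("bag")) {
    for (m in seq_len(p$n_learners)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(y[idx])) == 2L) break
      }
      members[[m]] <- fit_rpart(X[idx, , drop = FALSE], y[idx], p$max_splits)
    }
  } else if (method %in% c("adaboost", "rusboost")) {
    d <- rep(1 / n, n)
    yy <- ifelse(y == 1L, 1, -1)
    for (m in seq_len(p$n_learners)) {
      if (method == "rusboost") {
        # random under-sampling of the majority class, weight-proportional
        maj <- if (sum(y == 1L) >= sum(y == 0L)) 1L else 0L
        min_idx <- which(y != maj)
        maj_idx <- which(y == maj)
        take <- sample(maj_idx,
          size = min(length(maj_idx), length(min_idx)),
          prob = d[maj_idx] + 1e-12
        )
        idx <- c(min_idx, take)
        fitm <- fit_rpart(X[idx, , drop = FALSE], y[idx], p$max_splits,
          weights = d[idx] / sum(d[idx])
        )
      } else {
        fitm <- fit_rpart(X, y, p$max_splits, weights = d * n)
      }
      pred <- ifelse(predict_rpart_prob(fitm, X) >= 0.5, 1, -1)
      err <- sum(d[pred != yy])
      err <- min(max(err, 1e-10), 1 - 1e-10)
      alpha <- p$learn_rate * 0.5 * log((1 - err) / err)
      d <- d * exp(-alpha * yy * pred)
      d <- d / sum(d)
      members[[m]] <- fitm
      alphas[m] <- alpha
    }
  } else if (method %in% c("subspace_discriminant", "subspace_knn")) {
    dim_use <- min(p$subspace_dim, ncol(X))
    for (m in seq_len(p$n_learners)) {
      sub <- sort(sample.int(ncol(X), dim_use))
      subspaces[[m]] <- sub
      Xs <- X[, sub, drop = FALSE]
      members[[m]] <- if (method == "subspace_discriminant") {
        tryCatch(safe_da(Xs, y), error = function(e) NULL)
      } else {
        list(train = Xs, y = y, k = 10)
      }
    }
  } else {
    stop("unknown ensemble method `", method, "`", call. = FALSE)
  }
  list(members = members, alphas = alphas, subspaces = subspaces, method = method)
}

predict_ensemble <- function(fit, X) {
  p <- fit$preset$params
  method <- fit$method
  if (method == "bag") {
    probs <- vapply(
      fit$members, function(m) predict_rpart_prob(m, X),
      numeric(nrow(X))
    )
    if (is.null(dim(probs))) probs <- matrix(probs, nrow = nrow(X))
    rowMeans(probs)
  } else if (method %in% c("adaboost", "rusboost")) {
    F <- rep(0, nrow(X))
    for (m in seq_along(fit$members)) {
      h <- ifelse(predict_rpart_prob(fit$members[[m]], X) >= 0.5, 1, -1)
      F <- F + fit$alphas[m] * h
    }
    stats::plogis(2 * F)
  } else {
    probs <- vapply(seq_along(fit$members), function(m) {
      sub <- fit$subspaces[[m]]
      Xs <- X[, sub, drop = FALSE]
      mem <- fit$members[[m]]
      if (is.null(mem)) {
        return(rep(0.5, nrow(X)))
      }
      if (method == "subspace_discriminant") {
        pr <- predict(mem, Xs)$posterior
        if ("1" %in% colnames(pr)) pr[, "1"] else rep(0, nrow(X))
      } else {
        knn_score(mem$train, mem$y, Xs, mem$k, "euclidean", "equal")
      }
    }, numeric(nrow(X)))
    if (is.null(dim(probs))) probs <- matrix(probs, nrow = nrow(X))
    rowMeans(probs)
  }
}

# ---- cross-validation -------------------------------------------------------

#' Stratified k-fold cross-validation
#'
#' Seeded, label-stratified folds; each fold's model is fitted on the
#' training rows only (including the per-fold min-max feature rescaling, so
#' no information leaks from held-out rows) and predicts its held-out rows
#' exactly once.
#'
#' @param table Feature table with a binary `label` column; rows with missing
#'   feature values are dropped with a warning.
#' @param preset A [classifier_preset()] or preset name.
#' @param n_folds Number of folds (default 10); reduced with a warning when
#'   the smaller class has fewer members.
#' @param seed Integer seed making folds and stochastic learners
#'   reproducible.
#' @param features Feature columns. Default [feature_names()] present in the
#'   table.
#' @param label_col Label column name.
#' @param rescale Refit `[0, 1]` min-max scaling on each fold's training rows
#'   (default TRUE).
#' @return An object of class `cv_result`: predictions tibble (`row`, `fold`,
#'   `truth`, `pred`, `score`), the preset, and fold bookkeeping. See
#'   [glance.cv_result()] for pooled metrics.
#' @export
cross_validate <- function(table, preset, n_folds = 10, seed = NULL,
                           features = intersect(feature_names(), names(table)),
                           label_col = "label", rescale = TRUE) {
  if (is.character(preset)) preset <- classifier_preset(preset)
  stopifnot(inherits(preset, "classifier_preset"))
  X_all <- as.data.frame(table[features])
  y_all <- as.integer(table[[label_col]])
  complete <- stats::complete.cases(X_all)
  if (!all(complete)) {
    warning(sum(!complete), " row(s) with missing feature values dropped",
      call. = FALSE
    )
  }
  X_all <- as.matrix(X_all[complete, , drop = FALSE])
  y_all <- y_all[complete]
  rows <- which(complete)
  n <- length(y_all)
  counts <- table(factor(y_all, levels = c(0L, 1L)))
  if (min(counts) < 2L) stop("each class needs at least 2 rows", call. = FALSE)
  if (min(counts) < n_folds) {
    n_folds <- max(2L, as.integer(min(counts)))
    warning("fold count reduced to ", n_folds, " (small class)", call. = FALSE)
  }

  run <- function() {
    fold <- integer(n)
    for (cl in c(0L, 1L)) {
      idx <- sample(which(y_all == cl))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    preds <- vector("list", n_folds)
    for (f in seq_len(n_folds)) {
      tr <- fold != f
      te <- !tr
      Xtr <- X_all[tr, , drop = FALSE]
      Xte <- X_all[te, , drop = FALSE]
      if (rescale) {
        lo <- apply(Xtr, 2, min)
        hi <- apply(Xtr, 2, max)
        span <- ifelse(hi > lo, hi - lo, 1)
        Xtr <- sweep(sweep(Xtr, 2, lo), 2, span, "/")
        Xte <- sweep(sweep(Xte, 2, lo), 2, span, "/")
      }
      fit <- fit_model(Xtr, y_all[tr], preset)
      pr <- predict_model(fit, Xte)
      preds[[f]] <- tibble::tibble(
        row = rows[te], fold = f, truth = y_all[te],
        pred = pr$class, score = pr$score
      )
    }
    dplyr::arrange(dplyr::bind_rows(preds), .data$row)
  }
  predictions <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  structure(
    list(
      predictions = predictions, preset = preset, n_folds = n_folds,
      seed = seed, features = features
    ),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  acc <- mean(x$predictions$pred == x$predictions$truth)
  cat(sprintf(
    "<cv_result> %s, %d-fold: pooled accuracy %.3f on %d rows\n",
    x$preset$name, x$n_folds, acc, nrow(x$predictions)
  ))
  invisible(x)
}

#' Exhaustive feature-combination search
#'
#' Embedded-type feature selection: evaluates every feature combination of
#' the requested orders (default 2 to 5, plus the full set) with
#' [cross_validate()] and returns the accuracy-ordered table. For the
#' eight-feature set and default orders this is 211 combinations.
#'
#' @inheritParams cross_validate
#' @param orders Combination sizes to enumerate. Default `2:5`.
#' @param include_full Also evaluate the full feature set? Default TRUE.
#' @return A tibble with `features` (a `+`-joined name string), `n_features`
#'   and `accuracy`, sorted by decreasing accuracy.
#' @export
exhaustive_feature_search <- function(table, preset, orders = 2:5,
                                      include_full = TRUE, n_folds = 10,
                                      seed = NULL,
                                      features = intersect(feature_names(), names(table)),
                                      label_col = "label") {
  p <- length(features)
  combos <- list()
  for (k in orders[orders <= p]) {
    cmb <- utils::combn(features, k, simplify = FALSE)
    combos <- c(combos, cmb)
  }
  if (include_full && !any(vapply(combos, length, 0L) == p)) {
    combos <- c(combos, list(features))
  }
  acc <- vapply(combos, function(fts) {
    cv <- cross_validate(table, preset,
      n_folds = n_folds, seed = seed,
      features = fts, label_col = label_col
    )
    mean(cv$predictions$pred == cv$predictions$truth)
  }, numeric(1))
  tibble::tibble(
    features = vapply(combos, paste, "", collapse = "+"),
    n_features = vapply(combos, length, 0L),
    accuracy = acc
  ) |> dplyr::arrange(dplyr::desc(.data$accuracy))
}

#' Tune the ensemble classifier
#'
#' Seeded random search over the ensemble hyperparameters (method, learner
#' count, learning rate, split cap), scored by pooled cross-validated
#' accuracy. The default bagged-trees preset is always the first candidate,
#' so the tuned preset can never score below it on the evaluated set.
#'
#' @inheritParams cross_validate
#' @param budget Number of candidate configurations to evaluate (>= 1).
#' @return A list of class `tune_result`: `preset` (the winning
#'   [classifier_preset()]), `accuracy`, and the full `trace` tibble.
#' @export
tune_best <- function(table, budget = 25, seed = NULL, n_folds = 10,
                      features = intersect(feature_names(), names(table)),
                      label_col = "label") {
  stopifnot(budget >= 1)
  draw_candidates <- function() {
    cands <- list(list(name = "bagged_trees"))
    if (budget > 1) {
      for (i in seq_len(budget - 1)) {
        method <- sample(c("bag", "adaboost", "rusboost"), 1)
        cands[[i + 1]] <- list(
          name = switch(method,
            bag = "bagged_trees",
            adaboost = "boosted_trees",
            rusboost = "rusboosted_trees"
          ),
          n_learners = sample(10:60, 1),
          learn_rate = 10^stats::runif(1, -2, -0.3),
          max_splits = 2^sample(2:8, 1)
        )
      }
    }
    cands
  }
  cands <- if (is.null(seed)) {
    draw_candidates()
  } else {
    withr::with_seed(seed, draw_candidates())
  }
  trace <- purrr::imap(cands, function(cd, i) {
    prs <- do.call(classifier_preset, cd)
    cv_seed <- if (is.null(seed)) NULL else (as.integer(seed) + 17L) %% 2147483629L
    cv <- cross_validate(table, prs,
      n_folds = n_folds, seed = cv_seed,
      features = features, label_col = label_col
    )
    tibble::tibble(
      candidate = i, preset = prs$name,
      n_learners = prs$params$n_learners %||% 30,
      learn_rate = prs$params$learn_rate %||% 0.1,
      max_splits = prs$params$max_splits %||% 20,
      accuracy = mean(cv$predictions$pred == cv$predictions$truth)
    )
  }) |> dplyr::bind_rows()
  best_i <- which.max(trace$accuracy)
  structure(
    list(
      preset = do.call(classifier_preset, cands[[best_i]]),
      accuracy = trace$accuracy[best_i],
      trace = trace
    ),
    class = "tune_result"
  )
}
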
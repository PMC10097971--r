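# Independent brute-force reference implementations used as oracles.
# Deliberately naive (loops, direct definitions), sharing no code with the
# package internals they check.

# Direct windowed periodogram via an explicit DFT double sum, one-sided
# density normalization.
brute_periodogram <- function(x, window, fs) {
  N <- length(x)
  xw <- x * window
  half <- floor(N / 2) + 1L
  p <- numeric(half)
  for (k in seq_len(half)) {
    re <- 0
    im <- 0
    for (n in seq_len(N)) {
      ang <- -2 * pi * (n - 1) * (k - 1) / N
      re <- re + xw[n] * cos(ang)
      im <- im + xw[n] * sin(ang)
    }
    p[k] <- (re^2 + im^2) / (fs * sum(window^2))
  }
  mult <- rep(2, half)
  mult[1] <- 1
  if (N %% 2 == 0) mult[half] <- 1
  p * mult
}

# Literal transcription of the ReliefF weight-update recursion: k nearest
# hits and k nearest misses per class by L1 distance on range-normalized
# features, prior weighting P_n / (1 - P_p), processed over all rows.
brute_relieff <- function(X, y, k) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  rng <- apply(X, 2, function(c) max(c) - min(c))
  rng[rng == 0] <- 1
  Xn <- sweep(X, 2, rng, "/")
  classes <- sort(unique(y))
  priors <- sapply(classes, function(cl) mean(y == cl))
  W <- numeric(p)
  for (i in seq_len(n)) {
    for (ci in seq_along(classes)) {
      cl <- classes[ci]
      idx <- setdiff(which(y == cl), i)
      d <- sapply(idx, function(j) sum(abs(Xn[i, ] - Xn[j, ])))
      nb <- idx[order(d)[seq_len(k)]]
      for (f in seq_len(p)) {
        diff_sum <- sum(abs(Xn[i, f] - Xn[nb, f]))
        if (cl == y[i]) {
          W[f] <- W[f] - diff_sum / (k * n)
        } else {
          pn <- priors[ci]
          pp <- priors[match(y[i], classes)]
          W[f] <- W[f] + (pn / (1 - pp)) * diff_sum / (k * n)
        }
      }
    }
  }
  W
}

# AUC by exhaustive positive/negative pair comparison (ties count 1/2).
brute_auc <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# Plug-in mutual information with equal-frequency binning, written
# independently of the package's version.
brute_mi <- function(x, y, n_bins = 10) {
  cutef <- function(v) {
    if (length(unique(v)) <= n_bins) {
      return(as.integer(factor(v)))
    }
    br <- unique(quantile(v, seq(0, 1, length.out = n_bins + 1), names = FALSE))
    as.integer(cut(v, br, include.lowest = TRUE))
  }
  a <- cutef(x)
  b <- cutef(y)
  n <- length(x)
  mi <- 0
  for (i in unique(a)) {
    for (j in unique(b)) {
      pij <- sum(a == i & b == j) / n
      if (pij > 0) {
        mi <- mi + pij * log(pij / (sum(a == i) / n * sum(b == j) / n))
      }
    }
  }
  max(mi, 0)
}

# Naive greedy MRMR over the quotient criterion.
brute_mrmr_order <- function(X, y, n_bins = 10, eps = 1e-12) {
  p <- ncol(X)
  rel <- sapply(seq_len(p), function(j) brute_mi(X[[j]], y, n_bins))
  sel <- which.max(rel)
  rest <- setdiff(seq_len(p), sel)
  while (length(rest) > 0) {
    q <- sapply(rest, function(j) {
      red <- mean(sapply(sel, function(s) brute_mi(X[[j]], X[[s]], n_bins)))
      rel[j] / (red + eps)
    })
    pick <- rest[which.max(q)]
    sel <- c(sel, pick)
    rest <- setdiff(rest, pick)
  }
  names(X)[sel]
}

# Two-way ANOVA sums of squares computed from cell means by hand.
brute_anova2 <- function(y, f1, f2) {
  f1 <- factor(f1)
  f2 <- factor(f2)
  a <- nlevels(f1)
  b <- nlevels(f2)
  r <- length(y) / (a * b)
  grand <- mean(y)
  ss_a <- b * r * sum((tapply(y, f1, mean) - grand)^2)
  ss_b <- a * r * sum((tapply(y, f2, mean) - grand)^2)
  cell <- tapply(y, interaction(f1, f2), mean)
  ss_cells <- r * sum((cell - grand)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  ss_tot <- sum((y - grand)^2)
  ss_e <- ss_tot - ss_cells
  df_a <- a - 1
  df_b <- b - 1
  df_ab <- df_a * df_b
  df_e <- a * b * (r - 1)
  f_stat <- c(ss_a / df_a, ss_b / df_b, ss_ab / df_ab) / (ss_e / df_e)
  list(
    statistic = f_stat,
    p_value = pf(f_stat, c(df_a, df_b, df_ab), df_e, lower.tail = FALSE)
  )
}

# A small, valid feature table with both classes, for IO/classify tests.
make_feature_table <- function(n = 60, seed = 1, subject_id = "S01",
                               channel = "F8", informative = TRUE) {
  withr::with_seed(seed, {
    label <- rep(c(0L, 1L), length.out = n)
    shift <- if (informative) label else 0
    p_delta <- exp(rnorm(n, shift, 0.5))
    p_theta <- exp(rnorm(n, shift * 0.8, 0.5))
    p_alpha <- exp(rnorm(n, shift * 0.9, 0.5))
    p_beta <- exp(rnorm(n, -shift * 0.5, 0.5))
    tab <- tibble::tibble(
      subject_id = subject_id, channel = channel,
      window_index = seq_len(n) - 1L,
      p_delta = p_delta, p_theta = p_theta,
      p_alpha = p_alpha, p_beta = p_beta
    )
    dplyr::bind_cols(tab, compute_bpr(p_delta, p_theta, p_alpha, p_beta)[1:4]) |>
      dplyr::mutate(label = label)
  })
}
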
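test_that("mutual information matches closed forms and the independent oracle", {
  x <- as.numeric(1:100)
  expect_equal(mutual_information(x, x), log(10), tolerance = 1e-12)

  y <- rep(c(0, 1), 50)
  expect_equal(mutual_information(y, y), -2 * 0.5 * log(0.5), tolerance = 1e-12)

  withr::with_seed(21, {
    a <- rnorm(4000)
    b <- rnorm(4000)
    expect_lt(mutual_information(a, b), 0.03) # plug-in bias bound
  })
  expect_equal(mutual_information(rep(1, 50), rnorm(50)), 0)

  withr::with_seed(22, {
    u <- rnorm(200)
    v <- u + rnorm(200)
    expect_equal(mutual_information(u, v), brute_mi(u, v), tolerance = 1e-12)
  })
})

test_that("MRMR matches a brute-force greedy oracle and rewards relevance", {
  withr::with_seed(23, {
    n <- 200
    y <- rep(c(0L, 1L), each = n / 2)
    tab <- tibble::tibble(
      a = y + runif(n, 0, 0.2), # strong
      b = NA_real_, # duplicate of a, filled below
      c = y + runif(n, 0, 2), # weaker, partly independent signal
      d = rnorm(n), # noise
      label = y
    )
    tab$b <- tab$a
    rk <- mrmr_rank(tab, features = c("a", "b", "c", "d"))
    oracle <- brute_mrmr_order(tab[c("a", "b", "c", "d")], y)
    expect_equal(rk$feature, oracle)
    # the redundant duplicate is ranked below the weak independent feature
    expect_gt(which(rk$feature == "b"), which(rk$feature == "c"))
    expect_equal(rk$feature[1], "a")
  })
})

test_that("MRMR degenerate cases: pure noise scores low, label copy ranks first", {
  withr::with_seed(24, {
    n <- 500
    y <- rep(c(0L, 1L), each = n / 2)
    noise <- tibble::tibble(
      a = rnorm(n), b = rnorm(n), c = rnorm(n),
      label = y
    )
    rk <- mrmr_rank(noise, features = c("a", "b", "c"))
    expect_lt(max(rk$score[rk$rank == 1]), 0.1)

    withlab <- tibble::tibble(
      a = rnorm(n), exact = as.numeric(y), b = rnorm(n),
      label = y
    )
    rk2 <- mrmr_rank(withlab, features = c("a", "exact", "b"))
    expect_equal(rk2$feature[1], "exact")
  })
})

test_that("the chi-square statistic reproduces a hand-computed contingency table", {
  # 2 predictor bins x 2 classes with counts [[30,10],[10,30]]: chi2 = 20
  x <- rep(c(0, 1), each = 40)
  y <- c(rep(1, 30), rep(0, 10), rep(1, 10), rep(0, 30))
  res <- drowsEEG:::chi2_test(x, y)
  expect_equal(res$statistic, 20)
  expect_equal(res$df, 1L)
  expect_equal(res$p_value, pchisq(20, 1, lower.tail = FALSE))
  expect_lt(res$p_value, 0.05)
})

test_that("chi-square ranking marks significance and orders by score", {
  withr::with_seed(25, {
    n <- 300
    y <- rep(c(0L, 1L), each = n / 2)
    tab <- tibble::tibble(
      sep = y + runif(n, 0, 0.1), # perfectly separating
      weak = y + rnorm(n, sd = 3),
      noise = rnorm(n),
      label = y
    )
    rk <- chi2_rank(tab, features = c("sep", "weak", "noise"))
    expect_equal(rk$feature[1], "sep")
    expect_true(rk$significant[rk$feature == "sep"])
    expect_true(all(diff(rk$score) <= 0))
    expect_error(chi2_rank(tab[tab$label == 1, ], features = "sep"), "both classes")
  })
})

test_that("chi-square p-values are calibrated under the null", {
  withr::with_seed(26, {
    pvals <- vapply(seq_len(400), function(i) {
      x <- rnorm(100)
      y <- rep(c(0L, 1L), 50)
      drowsEEG:::chi2_test(x, y)$p_value
    }, numeric(1))
    type1 <- mean(pvals < 0.05)
    se <- sqrt(0.05 * 0.95 / 400)
    expect_lt(abs(type1 - 0.05), 3 * se)
  })
})

test_that("ReliefF weights match the brute-force recursion exactly on small data", {
  withr::with_seed(27, {
    for (rep_i in 1:4) {
      n <- sample(8:12, 1)
      k <- sample(1:3, 1)
      y <- c(rep(0L, ceiling(n / 2)), rep(1L, floor(n / 2)))
      X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("f1", "f2", "f3")))
      tab <- dplyr::bind_cols(tibble::as_tibble(X), tibble::tibble(label = y))
      rk <- relieff_rank(tab, features = c("f1", "f2", "f3"), k = k)
      ref <- brute_relieff(X, y, k)
      expect_equal(rk$score[match(c("f1", "f2", "f3"), rk$feature)], ref,
        tolerance = 1e-12
      )
    }
  })
})

test_that("ReliefF separates signal from noise and zeroes constant features", {
  withr::with_seed(28, {
    n <- 20
    y <- rep(c(0L, 1L), each = n / 2)
    tab <- tibble::tibble(
      sep = ifelse(y == 1, 1, 0) + runif(n, 0, 0.1),
      noise = runif(n),
      const = rep(2, n),
      label = y
    )
    rk <- relieff_rank(tab, features = c("sep", "noise", "const"), k = 1)
    w <- function(f) rk$score[rk$feature == f]
    expect_gt(w("sep"), 0.5)
    expect_lt(abs(w("noise")), 0.3)
    expect_equal(w("const"), 0)
    expect_true(all(rk$score >= -1 & rk$score <= 1))
  })
  small <- tibble::tibble(a = rnorm(6), label = rep(c(0L, 1L), 3))
  expect_warning(relieff_rank(small, features = "a", k = 10), "k reduced")
})

test_that("Z-score fusion standardizes each method and has exact zero mean", {
  mk <- function(scores, method) {
    out <- tibble::tibble(
      feature = paste0("f", seq_along(scores)),
      score = scores, method = method, rank = order(-scores)
    )
    class(out) <- c("feature_ranking", class(out))
    out
  }
  g <- gpi_rank(list(mk(c(1, 2, 3), "m1")))
  expect_equal(g$gpi[match(paste0("f", 1:3), g$feature)], c(-1, 0, 1))

  same <- gpi_rank(list(mk(c(5, 1, 3), "m1"), mk(c(5, 1, 3), "m2"), mk(c(5, 1, 3), "m3")))
  single <- gpi_rank(list(mk(c(5, 1, 3), "m1")))
  expect_equal(same$gpi, single$gpi)

  withr::with_seed(29, {
    r3 <- lapply(1:3, function(i) mk(runif(8), paste0("m", i)))
    g3 <- gpi_rank(r3)
    expect_equal(mean(g3$gpi), 0, tolerance = 1e-12)
    for (col in paste0("z_m", 1:3)) {
      expect_equal(mean(g3[[col]]), 0, tolerance = 1e-12)
      expect_equal(stats::sd(g3[[col]]), 1, tolerance = 1e-12)
    }
  })

  expect_warning(
    flat <- gpi_rank(list(mk(c(2, 2, 2), "m1"), mk(c(1, 2, 3), "m2"))),
    "zero score variance"
  )
  expect_true(all(flat$z_m1 == 0))
})

test_that("rankings are equivariant under feature permutation", {
  tab <- make_feature_table(n = 80, seed = 31)
  perm <- rev(feature_names())
  for (fun in list(mrmr_rank, chi2_rank, function(t, features) relieff_rank(t, features, k = 5))) {
    a <- fun(tab, feature_names())
    b <- fun(tab, perm)
    expect_equal(
      a$score[match(feature_names(), a$feature)],
      b$score[match(feature_names(), b$feature)],
      tolerance = 1e-12
    )
  }
})
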
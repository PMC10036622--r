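test_that("standardization gives zero-mean unit-sd rows and reports constant rows", {
  mat <- rbind(a = c(1, 2, 3), b = c(10, 20, 40), c = c(5, 5, 5))
  expect_warning(z <- standardize(mat), "constant")
  expect_equal(attr(z, "excluded"), "c")
  expect_equal(unname(rowMeans(z)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(z, 1, sd)), c(1, 1), tolerance = 1e-12)
  # idempotence
  z2 <- standardize(z)
  expect_equal(z2, z, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("order-1 B-spline weights are histogram indicators", {
  x <- c(0.1, 0.4, 0.9, 0.45, 0)
  w <- bspline_weights(x, k = 1, M = 4)
  expect_true(all(w %in% c(0, 1)))
  expect_equal(rowSums(w), rep(1, 5))
  # samples land in the expected bins of the observed range [0, 0.9]
  expect_equal(apply(w, 1, which.max), c(1, 2, 4, 3, 1))
})

test_that("B-spline weight rows are a partition of unity for varied (k, M)", {
  set.seed(11)
  for (k in c(1, 2, 3, 4)) {
    for (M in c(k, k + 1, k + 4, 12)) {
      w <- bspline_weights(rnorm(40), k, M)
      expect_equal(dim(w), c(40L, M))
      expect_true(all(w >= 0))
      expect_lt(max(abs(rowSums(w) - 1)), 1e-10)
    }
  }
  expect_error(bspline_weights(rep(2, 5), 3, 5), "zero-range")
  expect_error(bspline_weights(rnorm(5), 3, 2), "M must be >= k")
})

test_that("B-spline weights match an independent Cox-de Boor recursion", {
  set.seed(12)
  for (case in list(c(3, 3), c(3, 7), c(2, 5), c(4, 9))) {
    k <- case[1]; M <- case[2]
    x <- c(runif(30), 0, 1)          # include the domain endpoints
    w <- bspline_weights(x, k, M)
    knots <- bspline_knots(k, M)
    upper <- M - k + 1
    pos <- pmin(x * upper, upper * (1 - 1e-12))
    oracle <- sapply(seq_len(M), function(i) cox_de_boor(pos, i, k, knots))
    expect_equal(unname(w), unname(oracle), tolerance = 1e-9)
  }
  # the spec'd midpoint case: k = 3, M = 3, middle of the domain
  w_mid <- bspline_weights(c(0, 0.5, 1), 3, 3)[2, ]
  oracle_mid <- sapply(1:3, function(i)
    cox_de_boor(0.5, i, 3L, bspline_knots(3, 3)))
  expect_equal(unname(w_mid), oracle_mid, tolerance = 1e-12)
})

test_that("bin-selection rules are deterministic, symmetric, monotone and clamped", {
  x12 <- rnorm(12); y12 <- rnorm(12)
  x1k <- rnorm(1000); y1k <- rnorm(1000)
  expect_equal(select_bins(x12, y12, "fixed:10"), 10L)
  expect_equal(select_bins(x12, y12, "sturges", k = 3),
               select_bins(y12, x12, "sturges", k = 3))
  expect_gte(select_bins(x1k, y1k, "sturges"), select_bins(x12, y12, "sturges"))
  expect_gte(select_bins(x12, y12, "sturges", k = 3), 3L)
  expect_lte(select_bins(x12, y12, "sturges", k = 3), 6L)  # n/2 cap
  expect_error(select_bins(x12, y12, "nope"), "unknown bin rule")
})

test_that("plug-in MI matches closed-form discrete MI on bin-aligned data", {
  cfg <- mi_config(spline_order = 1, bin_rule = "fixed:2")
  # y = x, balanced halves: I = H = log 2
  x <- rep(c(0, 1), each = 10)
  expect_equal(mutual_information(x, x, cfg)$mi, log(2), tolerance = 1e-12)
  # the 2x2 table {0.4, 0.1; 0.1, 0.4} encoded as 10 samples
  xx <- rep(c(0, 1), each = 5)
  yy <- c(0, 0, 0, 0, 1, 0, 1, 1, 1, 1)
  joint <- matrix(c(0.4, 0.1, 0.1, 0.4), 2, byrow = TRUE)
  expect_equal(mutual_information(xx, yy, cfg)$mi, discrete_mi(joint),
               tolerance = 1e-9)
  expect_equal(discrete_mi(joint), 0.1927448, tolerance = 1e-6)
  # a 3x3 table with k = 1, M = 3
  cfg3 <- mi_config(spline_order = 1, bin_rule = "fixed:3")
  set.seed(21)
  xi <- sample(0:2, 60, replace = TRUE)
  yi <- ifelse(runif(60) < 0.5, xi, sample(0:2, 60, replace = TRUE))
  tab <- table(xi, yi) / 60
  expect_equal(mutual_information(xi, yi, cfg3)$mi,
               discrete_mi(unclass(tab)), tolerance = 1e-9)
})

test_that("MI is symmetric, nonnegative, and vanishes for independent data", {
  set.seed(22)
  x <- rnorm(200); y <- rnorm(200)
  cfg <- mi_config()
  expect_equal(mutual_information(x, y, cfg)$mi,
               mutual_information(y, x, cfg)$mi, tolerance = 1e-12)
  for (i in 1:20) {
    a <- rnorm(30); b <- rnorm(30)
    expect_gte(mutual_information(a, b, cfg)$mi, -1e-12)
  }
  # large-sample independence limit at the coarsest binning
  xi <- rnorm(10000); yi <- rnorm(10000)
  expect_lt(mutual_information(xi, yi,
                               mi_config(spline_order = 1,
                                         bin_rule = "fixed:2"))$mi, 0.01)
  expect_error(mutual_information(rnorm(5), rnorm(6)), "equal length")
})

test_that("independence permutation test detects strong dependence and is seeded", {
  set.seed(23)
  x <- rnorm(24)
  y <- x + 0.05 * rnorm(24)
  cfg <- mi_config(seed = 7)
  r1 <- permutation_test_independence(x, y, cfg)
  expect_equal(r1$p_value, 0)
  r2 <- permutation_test_independence(x, y, cfg)
  expect_identical(r1, r2)
  # p in [0, 1] and the add-one convention never returns 0
  r3 <- permutation_test_independence(x, y, mi_config(seed = 7, add_one = TRUE))
  expect_gt(r3$p_value, 0)
  expect_lte(r3$p_value, 1)
})

test_that("MI-difference test keeps the null when conditions are copies and has power", {
  set.seed(24)
  x <- rnorm(12); y <- x + 0.3 * rnorm(12)
  cfg <- mi_config(seed = 3, n_permutations = 200)
  same <- permutation_test_mi_difference(x, y, x, y, cfg)
  expect_equal(same$statistic, 0)
  expect_gte(same$p_value, 0.5)
  # determinism under seed
  expect_identical(same,
                   permutation_test_mi_difference(x, y, x, y, cfg))
  # power: condition 0 strongly dependent, condition 4 independent
  ps <- vapply(1:11, function(s) {
    set.seed(100 + s)
    x0 <- rnorm(12); y0 <- 0.95 * x0 + sqrt(1 - 0.95^2) * rnorm(12)
    x4 <- rnorm(12); y4 <- rnorm(12)
    permutation_test_mi_difference(x0, y0, x4, y4,
                                   mi_config(seed = s,
                                             n_permutations = 200))$p_value
  }, numeric(1))
  expect_lt(median(ps), 0.05)
  expect_error(permutation_test_mi_difference(rnorm(2), rnorm(2),
                                              rnorm(5), rnorm(5)),
               "at least 3")
})
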
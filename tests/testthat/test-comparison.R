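test_that("chi-squared histogram distance matches hand evaluation and its bounds", {
  expect_equal(chi2_histogram_distance(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(chi2_histogram_distance(c(1, 0), c(0, 1)), 1)
  expect_equal(chi2_histogram_distance(c(0.5, 0.5), c(1, 0)), 1 / 3)
  # symmetry and bounds on random normalized histograms
  set.seed(61)
  for (i in 1:25) {
    p <- runif(6); q <- runif(6)
    d1 <- chi2_histogram_distance(p, q)
    expect_equal(d1, chi2_histogram_distance(q, p), tolerance = 1e-12)
    expect_gte(d1, 0); expect_lte(d1, 1)
  }
  # zero-sum bins contribute nothing
  expect_equal(chi2_histogram_distance(c(0.5, 0.5, 0), c(1, 0, 0),
                                       normalize = FALSE), 1 / 3)
  expect_error(chi2_histogram_distance(c(1, 0), c(1, 0, 0)), "equal length")
  expect_error(chi2_histogram_distance(c(-1, 2), c(1, 0)), "nonnegative")
  expect_error(chi2_histogram_distance(c(0, 0), c(1, 0)), "all-zero")
})

test_that("net-change ranking orders by AtoP minus PtoA with stable ties", {
  rd <- matrix(c(5, 2, 0, 0,
                 1, 1, 0, 0,
                 0, 4, 0, 0), nrow = 3, byrow = TRUE,
               dimnames = list(c("X--X", "X--Y", "Y--Y"),
                               c("AtoP", "PtoA", "PtoP", "AtoA")))
  r <- net_change_ranking(rd)
  expect_equal(r$et, c("X--X", "X--Y", "Y--Y"))
  expect_equal(r$net, c(3, 0, -4))
  # all-zero: ties broken by catalog order
  r0 <- net_change_ranking(rd * 0)
  expect_equal(r0$et, c("X--X", "X--Y", "Y--Y"))
  # antisymmetry: swapping AtoP and PtoA reverses the ranking
  swapped <- rd[, c("PtoA", "AtoP", "PtoP", "AtoA")]
  colnames(swapped) <- c("AtoP", "PtoA", "PtoP", "AtoA")
  expect_equal(net_change_ranking(swapped)$et, rev(r$et))
})

test_that("CvM statistic matches brute-force ECDF evaluation", {
  # the 4-vs-4 separated case
  r <- cvm_two_sample(rep(1, 4), rep(10, 4))
  expect_equal(r$statistic, cvm_brute_force(rep(1, 4), rep(10, 4)),
               tolerance = 1e-12)
  # random continuous samples of unequal size
  set.seed(62)
  for (i in 1:10) {
    a <- rnorm(sample(5:30, 1)); b <- rnorm(sample(5:30, 1), mean = 0.5)
    expect_equal(cvm_two_sample(a, b)$statistic, cvm_brute_force(a, b),
                 tolerance = 1e-10)
  }
  # identical samples sit at the statistic's minimum and are not significant
  a <- rnorm(20)
  r_same <- cvm_two_sample(a, a)
  r_shift <- cvm_two_sample(a, a + 3)
  expect_lt(r_same$statistic, r_shift$statistic)
  expect_gt(r_same$p_value, 0.5)
  expect_error(cvm_two_sample(numeric(0), 1), "nonempty")
})

test_that("CvM asymptotic p-values reproduce an independent reference implementation", {
  # frozen from scipy.stats.cramervonmises_2samp (asymptotic), rng seed 1
  a <- c(0.345584, 0.821618, 0.330437, -1.303157, 0.905356, 0.446375,
         -0.536953, 0.581118, 0.364572, 0.294132, 0.028422, 0.546713,
         -0.736454, -0.16291, -0.482119, 0.598846, 0.039722, -0.292457,
         -0.781908, -0.257192, 0.008142, -0.275603, 1.294064, 1.006724,
         -2.711162, -1.889013, -0.174772, -0.42219, 0.213643, 0.217322)
  b <- c(2.917839, -0.312021, 0.422395, 2.842772, 1.446703, 1.463063,
         0.285994, -0.848075, 0.967465, 0.909014, -0.427352, 0.116773,
         0.727956, -0.144752, 0.70173, 0.895483, 0.835586, 0.293708,
         1.393748, 1.691167, 1.120848, -0.01823, 1.531652, 0.29856,
         1.679161)
  r <- cvm_two_sample(a, b)
  expect_equal(r$statistic, 1.0808484848484845, tolerance = 1e-10)
  expect_equal(r$p_value, 0.0015430334056425465, tolerance = 1e-8)
  r44 <- cvm_two_sample(rep(1, 4), rep(10, 4))
  expect_equal(r44$p_value, 0.0018673934648987256, tolerance = 1e-8)
})

test_that("CvM is invariant to order-preserving relabeling and roughly calibrated", {
  set.seed(63)
  a <- sample(1:10, 40, replace = TRUE)
  b <- sample(1:10, 35, replace = TRUE)
  relabel <- c(1, 3, 4, 10, 20, 21, 30, 44, 45, 90)  # monotone map
  r1 <- cvm_two_sample(a, b)
  r2 <- cvm_two_sample(relabel[a], relabel[b])
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-12)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
  # permutation p agrees in magnitude with asymptotic p on a clear case
  rp <- cvm_two_sample(rnorm(20), rnorm(20, 2), p_method = "permutation",
                       B = 400, seed = 2)
  expect_lt(rp$p_value, 0.05)
  # null calibration of the asymptotic p at moderate n: roughly uniform
  ps <- vapply(1:200, function(i) {
    set.seed(1000 + i)
    cvm_two_sample(sample(1:6, 25, replace = TRUE),
                   sample(1:6, 25, replace = TRUE))$p_value
  }, numeric(1))
  expect_gt(mean(ps > 0.5), 0.3)
  expect_lt(mean(ps < 0.05), 0.12)
})

test_that("ET-distribution comparison separates disjoint fingerprints", {
  catalog <- build_catalog(c("A", "B", "C", "D"))
  d_lo <- setNames(c(30, 25, 20, 0, 0, 0, 0, 0, 0, 0), catalog$et)
  d_hi <- setNames(c(0, 0, 0, 0, 0, 0, 0, 20, 25, 30), catalog$et)
  r <- compare_et_distributions(d_lo, d_hi, bonferroni = 6)
  expect_lt(r$p_value, 0.05)
  r_same <- compare_et_distributions(d_lo, d_lo)
  expect_gt(r_same$p_value, 0.5)
  # Bonferroni cap at 1
  r_cap <- compare_et_distributions(d_lo, d_lo, bonferroni = 6)
  expect_equal(r_cap$p_value, 1)
  expect_error(compare_et_distributions(d_lo * 0, d_hi), "zero total")
})

test_that("Torgerson MDS recovers Euclidean configurations and agrees with cmdscale", {
  # two points at distance d embed with separation exactly d
  D2 <- matrix(c(0, 3.7, 3.7, 0), 2)
  x2 <- torgerson_mds(D2, dim = 1)
  expect_equal(abs(x2[1, 1] - x2[2, 1]), 3.7, tolerance = 1e-12)
  # planar points: pairwise distances reproduced to 1e-9
  set.seed(64)
  pts <- matrix(rnorm(10), 5, 2)
  D <- as.matrix(dist(pts))
  X <- torgerson_mds(D, dim = 2)
  expect_equal(as.matrix(dist(X)), D, tolerance = 1e-9,
               ignore_attr = TRUE)
  # cross-check against the base implementation of classical scaling
  X_ref <- cmdscale(D, k = 2)
  expect_equal(abs(X), abs(X_ref), tolerance = 1e-9, ignore_attr = TRUE)
  # sign convention: largest-magnitude loading positive in each column
  for (cix in 1:2) expect_gt(X[which.max(abs(X[, cix])), cix], 0)
  # all-zero distances -> all points at the origin
  Z <- suppressWarnings(torgerson_mds(matrix(0, 3, 3)))
  expect_true(all(Z == 0))
  expect_error(torgerson_mds(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("ET distance matrices are symmetric, zero-diagonal and bounded", {
  set.seed(65)
  rd <- matrix(runif(20), nrow = 5,
               dimnames = list(paste0("e", 1:5), response_fates()))
  D <- et_distance_matrix(rd)
  expect_equal(D, t(D))
  expect_equal(diag(D), setNames(rep(0, 5), paste0("e", 1:5)))
  expect_true(all(D >= 0 & D <= 1))
  # 3-bin variant drops the AtoA column
  D3 <- et_distance_matrix(rd, include_absent = FALSE)
  expect_false(identical(D, D3))
})
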
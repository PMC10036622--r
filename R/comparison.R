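#' Chi-squared histogram distance
#'
#' \eqn{\chi^2(P, Q) = \frac{1}{2}\sum_i (P_i - Q_i)^2 / (P_i + Q_i)} over
#' aligned, normalized histograms. Bounded in \eqn{[0, 1]}: 0 iff the two
#' normalized histograms are equal, 1 iff their supports are disjoint. Bins
#' with \eqn{P_i + Q_i = 0} contribute 0. Not a metric (the triangle
#' inequality may fail); symmetric by construction.
#'
#' @param p,q nonnegative vectors over the same bins.
#' @param normalize divide each histogram by its total first (default TRUE;
#'   an all-zero histogram is invalid).
#' @return distance in \eqn{[0, 1]}.
#' @export
chi2_histogram_distance <- function(p, q, normalize = TRUE) {
  if (length(p) != length(q)) stop("histograms must have equal length")
  if (any(p < 0) || any(q < 0)) stop("histogram entries must be nonnegative")
  if (normalize) {
    if (sum(p) == 0 || sum(q) == 0) stop("all-zero histogram")
    p <- p / sum(p); q <- q / sum(q)
  }
  tot <- p + q
  nz <- tot > 0
  0.5 * sum((p[nz] - q[nz])^2 / tot[nz])
}

#' Net-change ranking of edge types
#'
#' Ranks ETs by the weighted \code{AtoP} count minus the weighted
#' \code{PtoA} count, descending. A positive net change means a net gain of
#' edges in the later condition; ties break lexicographically by catalog
#' index (stable and documented).
#'
#' @param resp_dist matrix from
#'   \code{\link{response_distribution_per_et}} (rows = ETs, columns
#'   include \code{AtoP} and \code{PtoA}).
#' @return data frame sorted by rank: \code{rank}, \code{et}, \code{AtoP},
#'   \code{PtoA}, \code{net}.
#' @export
net_change_ranking <- function(resp_dist) {
  net <- resp_dist[, "AtoP"] - resp_dist[, "PtoA"]
  ord <- order(-net, seq_along(net))
  data.frame(rank = seq_along(net), et = rownames(resp_dist)[ord],
             AtoP = resp_dist[ord, "AtoP"], PtoA = resp_dist[ord, "PtoA"],
             net = net[ord], row.names = NULL, stringsAsFactors = FALSE)
}

# CDF of the limiting distribution of the Cramér-von Mises statistic
# (integral of a squared Brownian bridge), via the classical Bessel-K series.
cvm_limit_cdf <- function(x, n_terms = 12L) {
  vapply(x, function(xx) {
    if (xx <= 0) return(0)
    if (xx > 20) return(1)
    k <- 0:(n_terms - 1L)
    a <- exp(lgamma(k + 0.5) - lgamma(0.5) - lgamma(k + 1))
    z <- (4 * k + 1)^2 / (16 * xx)
    terms <- a * sqrt(4 * k + 1) * exp(-2 * z) *
      besselK(z, 0.25, expon.scaled = TRUE)
    min(1, max(0, sum(terms) / (pi * sqrt(xx))))
  }, numeric(1))
}

#' Two-sample Cramér-von Mises test
#'
#' Tests whether two samples are drawn from the same distribution, using the
#' rank form of the two-sample Cramér-von Mises statistic (midranks for
#' ties):
#' \deqn{T = \frac{U}{nm(n+m)} - \frac{4nm - 1}{6(n+m)}, \quad
#'   U = n\sum_i (r_i - i)^2 + m\sum_j (s_j - j)^2,}
#' equivalent to the integrated squared difference of the two empirical
#' distribution functions over the pooled sample. The p-value comes either
#' from the statistic's asymptotic limiting distribution (after centering
#' and scaling the finite-sample statistic to the limit's mean 1/6 and
#' variance 1/45) or from a seeded permutation re-splitting of the pooled
#' sample.
#'
#' @param a,b numeric (or ordinal) samples; nonempty.
#' @param p_method \code{"asymptotic"} or \code{"permutation"}.
#' @param B permutations when \code{p_method = "permutation"}.
#' @param seed seed for the permutation p-value.
#' @param bonferroni family-size multiplier applied to the p-value (capped
#'   at 1).
#' @return list with \code{statistic} (reported as the A² value),
#'   \code{p_value}, \code{correction}, \code{method}.
#' @export
cvm_two_sample <- function(a, b, p_method = c("asymptotic", "permutation"),
                           B = 1000L, seed = 1L, bonferroni = 1) {
  p_method <- match.arg(p_method)
  if (!length(a) || !length(b)) stop("both samples must be nonempty")
  stat <- cvm_statistic(a, b)
  n <- length(a); m <- length(b)
  if (p_method == "asymptotic") {
    et <- (1 + 1 / (n + m)) / 6
    vt <- (1 / 45) * (m + n + 1) / (m + n)^2 *
      (4 * m * n * (m + n) - 3 * (m^2 + n^2) - 2 * m * n) / (4 * m * n)
    tn <- 1 / 6 + (stat - et) / sqrt(45 * vt)
    p <- if (tn < 0.003) 1 else max(0, 1 - cvm_limit_cdf(tn))
  } else {
    pooled <- c(a, b)
    old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
    set.seed(seed)
    null_stat <- vapply(seq_len(B), function(i) {
      idx <- sample.int(n + m)
      cvm_statistic(pooled[idx[seq_len(n)]], pooled[idx[n + seq_len(m)]])
    }, numeric(1))
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    p <- (sum(null_stat >= stat) + 1) / (B + 1)
  }
  list(statistic = stat, p_value = min(1, p * bonferroni),
       correction = bonferroni, method = p_method)
}

# Rank form of the two-sample CvM statistic (Anderson's U), midranks on ties.
cvm_statistic <- function(a, b) {
  n <- length(a); m <- length(b)
  pooled_ranks <- rank(c(a, b))
  r <- sort(pooled_ranks[seq_len(n)])
  s <- sort(pooled_ranks[n + seq_len(m)])
  U <- n * sum((r - seq_len(n))^2) + m * sum((s - seq_len(m))^2)
  U / (n * m * (n + m)) - (4 * n * m - 1) / (6 * (n + m))
}

#' Compare two edge-type distributions with the Cramér-von Mises test
#'
#' Treats the catalog-ordered ETs as ordinal categories: each weighted count
#' is rounded to the nearest multiple of \code{resolution} and expanded into
#' that many replicated ordinal observations (the ET's catalog index), then
#' the two ordinal samples are compared with
#' \code{\link{cvm_two_sample}}.
#'
#' @param dist_a,dist_b \code{et_distribution}s over a common catalog.
#' @param resolution weight-rounding resolution (default 1).
#' @param bonferroni family-size multiplier for the p-value.
#' @param ... passed to \code{\link{cvm_two_sample}}.
#' @return list as from \code{\link{cvm_two_sample}}.
#' @export
compare_et_distributions <- function(dist_a, dist_b, resolution = 1,
                                     bonferroni = 1, ...) {
  if (length(dist_a) != length(dist_b))
    stop("distributions must share a catalog")
  expand <- function(d) {
    counts <- round(as.numeric(d) / resolution)
    if (sum(counts) == 0) stop("distribution has zero total after rounding")
    rep(seq_along(counts), times = counts)
  }
  cvm_two_sample(expand(dist_a), expand(dist_b), bonferroni = bonferroni,
                 ...)
}

#' Pairwise chi-squared distance matrix between per-ET fate histograms
#'
#' Builds the symmetric ET-by-ET matrix of chi-squared histogram distances
#' between the fate histograms of the selected ETs of one response network.
#'
#' @param resp_dist matrix from
#'   \code{\link{response_distribution_per_et}}.
#' @param ets ET IDs (rownames) to include; default all with positive total.
#' @param include_absent include the \code{AtoA} bin (default TRUE; FALSE
#'   restricts to the three response-edge fates).
#' @return symmetric matrix of distances with zero diagonal.
#' @export
et_distance_matrix <- function(resp_dist, ets = NULL, include_absent = TRUE) {
  cols <- if (include_absent) response_fates()
          else setdiff(response_fates(), "AtoA")
  h <- resp_dist[, cols, drop = FALSE]
  if (is.null(ets)) ets <- rownames(h)[rowSums(h) > 0]
  h <- h[ets, , drop = FALSE]
  if (any(rowSums(h) == 0)) stop("selected ET with all-zero histogram")
  t_ <- nrow(h)
  D <- matrix(0, t_, t_, dimnames = list(ets, ets))
  for (i in seq_len(t_)) for (j in seq_len(t_)) {
    if (j > i) D[i, j] <- D[j, i] <- chi2_histogram_distance(h[i, ], h[j, ])
  }
  D
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Embeds a symmetric distance matrix into \code{dim} dimensions by
#' eigendecomposition of the double-centered squared-distance matrix
#' \eqn{B = -\frac{1}{2} C D^{(2)} C}: coordinates are the top eigenvectors
#' scaled by the square roots of their (positive) eigenvalues, which
#' minimizes \eqn{\sum_{ij} (z_{ij} - \sum_m x_{im} x_{jm})^2}. Negative
#' eigenvalues (non-Euclidean input) are truncated and reported. For
#' reproducibility across eigensolvers, each coordinate column's
#' largest-magnitude loading is made positive.
#'
#' @param D symmetric distance matrix with zero diagonal.
#' @param dim requested embedding dimension (default 2). If fewer positive
#'   eigenvalues exist, fewer columns are returned with a warning.
#' @return coordinate matrix (rows = objects); attribute
#'   \code{"eigenvalues"} holds the full eigenvalue spectrum.
#' @export
torgerson_mds <- function(D, dim = 2L) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D) || max(abs(D - t(D))) > 1e-8 ||
      max(abs(diag(D))) > 1e-8)
    stop("D must be symmetric with zero diagonal")
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  Bmat <- -0.5 * J %*% (D^2) %*% J
  eg <- eigen((Bmat + t(Bmat)) / 2, symmetric = TRUE)
  pos <- which(eg$values > max(eg$values[1], 0) * 1e-12 & eg$values > 0)
  k <- min(dim, length(pos))
  if (k < dim)
    warning(sprintf("only %d positive eigenvalue(s); returning %d dimension(s)",
                    length(pos), k))
  if (k == 0L) {
    coords <- matrix(0, n, max(1L, dim), dimnames = list(rownames(D), NULL))
  } else {
    coords <- eg$vectors[, seq_len(k), drop = FALSE] %*%
      diag(sqrt(eg$values[seq_len(k)]), k)
    for (cix in seq_len(k)) {
      imax <- which.max(abs(coords[, cix]))
      if (coords[imax, cix] < 0) coords[, cix] <- -coords[, cix]
    }
    rownames(coords) <- rownames(D)
  }
  attr(coords, "eigenvalues") <- eg$values
  coords
}
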
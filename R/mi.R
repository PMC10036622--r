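#' Configuration for the mutual-information estimator
#'
#' Bundles the B-spline order, the per-pair bin-number rule, the number of
#' permutations for the two hypothesis tests and the root random seed.
#'
#' @param spline_order B-spline order \eqn{k} (order = degree + 1); the
#'   default 3 gives piecewise-quadratic bases. \code{spline_order = 1}
#'   reduces the estimator to an ordinary histogram.
#' @param bin_rule either the name of a registered rule (\code{"sturges"},
#'   \code{"sqrt"}) or \code{"fixed:M"} for a constant number of bins.
#' @param n_permutations number of permutations \eqn{B} used to build the
#'   empirical null distribution of each test.
#' @param seed root integer seed. Per-pair seeds are derived from it and the
#'   sorted molecule IDs, so results are independent of evaluation order.
#' @param add_one if \code{TRUE}, p-values use the \eqn{(c+1)/(B+1)}
#'   convention instead of the plain ratio \eqn{c/B} (which can be 0).
#'
#' @return an object of class \code{mi_config}.
#' @export
mi_config <- function(spline_order = 3L, bin_rule = "sturges",
                      n_permutations = 500L, seed = 1L, add_one = FALSE) {
  spline_order <- as.integer(spline_order)
  n_permutations <- as.integer(n_permutations)
  if (spline_order < 1L) stop("spline_order must be >= 1")
  if (n_permutations < 1L) stop("n_permutations must be >= 1")
  structure(list(spline_order = spline_order, bin_rule = bin_rule,
                 n_permutations = n_permutations, seed = as.integer(seed),
                 add_one = isTRUE(add_one)),
            class = "mi_config")
}

#' Row-wise standardization of an abundance matrix
#'
#' Centers and scales every molecule (row) to mean 0 and sample standard
#' deviation 1. Constant rows cannot be standardized; they are removed and
#' reported via the \code{"excluded"} attribute (with a warning), never
#' silently dropped.
#'
#' @param mat numeric matrix, molecules in rows, samples in columns; rownames
#'   are molecule IDs.
#' @return the standardized matrix with attribute \code{"excluded"} holding
#'   the IDs of constant rows.
#' @export
standardize <- function(mat) {
  mat <- as.matrix(mat)
  if (is.null(rownames(mat))) rownames(mat) <- as.character(seq_len(nrow(mat)))
  if (anyDuplicated(rownames(mat))) stop("duplicate molecule IDs")
  sds <- apply(mat, 1L, sd)
  constant <- !is.finite(sds) | sds == 0
  if (any(constant)) {
    warning(sprintf("excluding %d constant molecule(s): %s",
                    sum(constant),
                    paste(head(rownames(mat)[constant], 5L), collapse = ", ")))
  }
  out <- mat[!constant, , drop = FALSE]
  out <- t(scale(t(out)))
  attr(out, "excluded") <- rownames(mat)[constant]
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  out
}

#' B-spline basis weights for a sample vector
#'
#' Maps the sample values linearly from their observed range onto the knot
#' domain and evaluates the \eqn{M} B-spline basis functions of order
#' \eqn{k} at each mapped position. Rows are a partition of unity (sum to 1),
#' so each sample spreads one unit of mass over up to \eqn{k} adjacent bins;
#' with \eqn{k = 1} this is ordinary histogram binning.
#'
#' @param x numeric vector (finite, non-constant).
#' @param k spline order, \eqn{k \ge 1}.
#' @param M number of basis functions (bins), \eqn{M \ge k}.
#' @return an \code{n x M} matrix of nonnegative weights, rows summing to 1.
#' @export
bspline_weights <- function(x, k = 3L, M) {
  k <- as.integer(k); M <- as.integer(M)
  if (k < 1L) stop("k must be >= 1")
  if (M < k) stop("M must be >= k")
  if (!all(is.finite(x))) stop("x must be finite")
  rng <- range(x)
  if (rng[1L] == rng[2L]) stop("zero-range input: all values equal")
  upper <- M - k + 1L
  pos <- (x - rng[1L]) / (rng[2L] - rng[1L]) * upper
  # B-spline bases are right-open at the final knot; nudge the maximum inside
  pos <- pmin(pos, upper * (1 - 1e-12))
  knots <- c(rep(0, k), seq_len(M - k), rep(upper, k))
  splines::splineDesign(knots, pos, ord = k)
}

# Registered bin-number rules. Both depend only on the common sample size, so
# they are symmetric in (x, y) by construction; all are clamped to
# [k, max(k, floor(n/2))].
bin_rules <- list(
  sturges = function(n) ceiling(log2(n)) + 1L,
  sqrt    = function(n) floor(sqrt(n))
)

#' Choose the number of bins for one variable pair
#'
#' @param x,y the two sample vectors (same length).
#' @param rule rule name: \code{"sturges"} (default; \eqn{\lceil \log_2 n
#'   \rceil + 1}), \code{"sqrt"}, or \code{"fixed:M"}.
#' @param k spline order used as the lower clamp (\eqn{M \ge k}).
#' @return integer \eqn{M}.
#' @export
select_bins <- function(x, y, rule = "sturges", k = 3L) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (startsWith(rule, "fixed:")) {
    M <- as.integer(sub("^fixed:", "", rule))
    if (is.na(M)) stop("unparseable fixed rule: ", rule)
  } else {
    fn <- bin_rules[[rule]]
    if (is.null(fn)) stop("unknown bin rule: ", rule)
    M <- as.integer(fn(n))
    M <- min(M, max(as.integer(k), n %/% 2L))
  }
  max(M, as.integer(k))
}

# Plug-in MI (nats) from two weight matrices sharing the sample dimension.
# joint(i, j) = mean over samples of w_x[, i] * w_y[, j]; zero cells
# contribute zero.
mi_from_weights <- function(wx, wy) {
  n <- nrow(wx)
  joint <- crossprod(wx, wy) / n
  px <- colSums(wx) / n
  py <- colSums(wy) / n
  denom <- outer(px, py)
  nz <- joint > 0
  sum(joint[nz] * log(joint[nz] / denom[nz]))
}

#' B-spline mutual information between two sample vectors
#'
#' Estimates \eqn{I(X;Y) = \sum_{ij} \hat p(i,j) \log[\hat p(i,j) /
#' (\hat p_x(i)\,\hat p_y(j))]} in nats, where the joint cell probabilities
#' are the sample means of outer products of per-sample B-spline weight rows.
#'
#' @param x,y numeric vectors of equal length \eqn{n \ge 3}.
#' @param cfg an \code{\link{mi_config}}.
#' @param M optional fixed bin number overriding the configured rule.
#' @return list with elements \code{mi} (nats) and \code{M_used}.
#' @export
mutual_information <- function(x, y, cfg = mi_config(), M = NULL) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 samples")
  M <- M %||% select_bins(x, y, cfg$bin_rule, cfg$spline_order)
  wx <- bspline_weights(x, cfg$spline_order, M)
  wy <- bspline_weights(y, cfg$spline_order, M)
  list(mi = mi_from_weights(wx, wy), M_used = as.integer(M))
}

#' Permutation test of statistical independence
#'
#' Tests the null hypothesis \eqn{I(X;Y) = 0} (statistical independence).
#' The null distribution is built from \eqn{B} recomputations of the MI after
#' independent uniform random permutations of \code{x} (\code{y} fixed); the
#' p-value is the fraction of null samples strictly larger than the observed
#' MI (or \eqn{(c+1)/(B+1)} when \code{cfg$add_one}).
#'
#' @inheritParams mutual_information
#' @param seed optional integer seed overriding \code{cfg$seed} (used by the
#'   network layer to inject per-pair seeds).
#' @return list with \code{mi}, \code{p_value}, \code{M_used}, \code{B}.
#' @export
permutation_test_independence <- function(x, y, cfg = mi_config(),
                                          seed = NULL) {
  n <- length(x)
  M <- select_bins(x, y, cfg$bin_rule, cfg$spline_order)
  wx <- bspline_weights(x, cfg$spline_order, M)
  wy <- bspline_weights(y, cfg$spline_order, M)
  obs <- mi_from_weights(wx, wy)
  B <- cfg$n_permutations
  null_mi <- numeric(B)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(seed %||% cfg$seed)
  for (b in seq_len(B)) {
    null_mi[b] <- mi_from_weights(wx[sample.int(n), , drop = FALSE], wy)
  }
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  count <- sum(null_mi > obs)
  p <- if (cfg$add_one) (count + 1) / (B + 1) else count / B
  list(mi = obs, p_value = p, M_used = as.integer(M), B = B)
}

#' Permutation test for a difference in mutual information between conditions
#'
#' Tests \eqn{H_0: I_{0}(X;Y) = I_{4}(X;Y)} for one molecule pair measured
#' under two conditions. The statistic is \eqn{|I_0 - I_4|}. Null samples are
#' generated by pooling the paired \eqn{(x, y)} observations of both
#' conditions and randomly re-splitting them into groups of the original
#' sizes, which preserves the within-sample pairing while enforcing the null.
#'
#' @param x0,y0 paired vectors for condition 0.
#' @param x4,y4 paired vectors for condition 4 (sizes may differ).
#' @param cfg an \code{\link{mi_config}}.
#' @param seed optional integer seed overriding \code{cfg$seed}.
#' @return list with \code{statistic} (\eqn{|I_0 - I_4|}), \code{p_value},
#'   \code{mi_0}, \code{mi_4}.
#' @export
permutation_test_mi_difference <- function(x0, y0, x4, y4,
                                           cfg = mi_config(), seed = NULL) {
  n0 <- length(x0); n4 <- length(x4)
  if (length(y0) != n0 || length(y4) != n4) stop("paired vectors must match")
  if (n0 < 3L || n4 < 3L) stop("need at least 3 samples per condition")
  mi0 <- mutual_information(x0, y0, cfg)$mi
  mi4 <- mutual_information(x4, y4, cfg)$mi
  obs <- abs(mi0 - mi4)
  px <- c(x0, x4); py <- c(y0, y4)
  B <- cfg$n_permutations
  null_stat <- numeric(B)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(seed %||% cfg$seed)
  for (b in seq_len(B)) {
    idx <- sample.int(n0 + n4)
    g0 <- idx[seq_len(n0)]
    g4 <- idx[n0 + seq_len(n4)]
    null_stat[b] <- abs(mutual_information(px[g0], py[g0], cfg)$mi -
                        mutual_information(px[g4], py[g4], cfg)$mi)
  }
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  count <- sum(null_stat > obs)
  p <- if (cfg$add_one) (count + 1) / (B + 1) else count / B
  list(statistic = obs, p_value = p, mi_0 = mi0, mi_4 = mi4)
}
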
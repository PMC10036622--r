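#' Maximum number of edges of a simple undirected graph
#'
#' The full-connection edge count \eqn{\binom{N}{2} = N(N-1)/2}: the number
#' of edges when every pair of the \eqn{N} nodes is connected.
#'
#' @param N number of nodes, \eqn{N \ge 1}.
#' @return \eqn{N(N-1)/2}.
#' @export
full_connection_count <- function(N) {
  if (any(N < 1)) stop("N must be >= 1")
  N * (N - 1) / 2
}

#' Infer a mutual-information network from one condition's matrix
#'
#' Runs the permutation test of independence on all \eqn{N(N-1)/2} molecule
#' pairs of the (standardized) matrix and connects the pairs whose p-value
#' falls strictly below the threshold \code{p0}. Constant molecules are
#' excluded from pairwise analysis and reported in the result; per-pair
#' permutation seeds are derived from the root seed and the sorted molecule
#' IDs, so the result does not depend on evaluation order.
#'
#' @param mat molecule x sample matrix (rownames = molecule IDs).
#' @param cfg an \code{\link{mi_config}}.
#' @param p0 edge-existence threshold on the p-value (default 0.05).
#' @return an object of class \code{mi_network}: fields \code{nodes},
#'   \code{pairs} (data frame over all tested pairs: \code{a}, \code{b},
#'   \code{mi}, \code{p}, \code{M}), \code{p0}, \code{excluded},
#'   \code{config}.
#' @export
infer_network <- function(mat, cfg = mi_config(), p0 = 0.05) {
  if (!all(is.finite(mat))) stop("matrix contains non-finite values")
  if (ncol(mat) < 3L) stop("need at least 3 samples")
  z <- standardize(mat)
  excluded <- attr(z, "excluded")
  ids <- rownames(z)
  m <- length(ids)
  n_pairs <- m * (m - 1) %/% 2
  a <- character(n_pairs); b <- character(n_pairs)
  mi <- numeric(n_pairs); p <- numeric(n_pairs); M <- integer(n_pairs)
  idx <- 0L
  # weight matrices per (molecule, M); the bin rules in use depend only on n,
  # so in practice one entry per molecule
  wcache <- new.env(parent = emptyenv())
  get_w <- function(i, Mi) {
    key <- paste0(i, ":", Mi)
    w <- get0(key, envir = wcache, inherits = FALSE)
    if (is.null(w)) {
      w <- bspline_weights(z[i, ], cfg$spline_order, Mi)
      assign(key, w, envir = wcache)
    }
    w
  }
  B <- cfg$n_permutations
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  n <- ncol(z)
  for (i in seq_len(m - 1L)) {
    for (j in seq.int(i + 1L, m)) {
      idx <- idx + 1L
      Mij <- select_bins(z[i, ], z[j, ], cfg$bin_rule, cfg$spline_order)
      wx <- get_w(i, Mij); wy <- get_w(j, Mij)
      obs <- mi_from_weights(wx, wy)
      set.seed(pair_seed(cfg$seed, ids[i], ids[j]))
      count <- 0L
      for (bb in seq_len(B)) {
        if (mi_from_weights(wx[sample.int(n), , drop = FALSE], wy) > obs)
          count <- count + 1L
      }
      a[idx] <- ids[i]; b[idx] <- ids[j]
      mi[idx] <- obs
      p[idx] <- if (cfg$add_one) (count + 1) / (B + 1) else count / B
      M[idx] <- Mij
    }
  }
  structure(list(nodes = ids,
                 pairs = data.frame(a = a, b = b, mi = mi, p = p, M = M,
                                    stringsAsFactors = FALSE),
                 p0 = p0, excluded = excluded, config = cfg),
            class = "mi_network")
}

#' Re-threshold an inferred network
#'
#' Rebuilds the edge set from the stored per-pair p-values at a new
#' threshold, without re-running any permutation.
#'
#' @param net an \code{mi_network}.
#' @param p0 new threshold.
#' @return the network with updated \code{p0}.
#' @export
set_threshold <- function(net, p0) {
  stopifnot(inherits(net, "mi_network"))
  net$p0 <- p0
  net
}

#' Present edges of a network
#'
#' @param net an \code{mi_network}.
#' @return data frame of pairs with \eqn{p < p_0}.
#' @export
network_edges <- function(net) {
  net$pairs[net$pairs$p < net$p0, , drop = FALSE]
}

#' @export
print.mi_network <- function(x, ...) {
  e <- nrow(network_edges(x))
  n <- length(x$nodes)
  cat(sprintf("MI network: %d nodes, %d/%d edges at p0 = %g (density %.2f%%)\n",
              n, e, nrow(x$pairs), x$p0,
              100 * e / full_connection_count(n)))
  if (length(x$excluded))
    cat("  excluded constant molecules:", length(x$excluded), "\n")
  invisible(x)
}

#' Response network: the difference between two condition networks
#'
#' Assigns every unordered pair of distinct nodes exactly one of four fates:
#' \code{PtoP} (edge in both networks), \code{PtoA} (only in the first),
#' \code{AtoP} (only in the second), \code{AtoA} (in neither). \code{PtoP},
#' \code{PtoA} and \code{AtoP} pairs are the response edges.
#'
#' @param net0 network of the earlier condition (e.g. before perturbation).
#' @param net4 network of the later condition; must share the node set.
#' @return an object of class \code{response_network}: \code{nodes} and a
#'   \code{pairs} data frame (\code{a}, \code{b}, \code{fate}).
#' @export
response_network <- function(net0, net4) {
  stopifnot(inherits(net0, "mi_network"), inherits(net4, "mi_network"))
  if (!identical(sort(net0$nodes), sort(net4$nodes)))
    stop("node sets differ between the two networks")
  e0 <- pair_key(network_edges(net0)$a, network_edges(net0)$b)
  e4 <- pair_key(network_edges(net4)$a, network_edges(net4)$b)
  pairs <- net0$pairs[, c("a", "b")]
  key <- pair_key(pairs$a, pairs$b)
  in0 <- key %in% e0
  in4 <- key %in% e4
  pairs$fate <- ifelse(in0 & in4, "PtoP",
                ifelse(in0 & !in4, "PtoA",
                ifelse(!in0 & in4, "AtoP", "AtoA")))
  structure(list(nodes = net0$nodes, pairs = pairs),
            class = "response_network")
}

#' Fates constant
#' @return the four fate labels in canonical order.
#' @export
response_fates <- function() c("PtoP", "AtoP", "PtoA", "AtoA")

#' @export
print.response_network <- function(x, ...) {
  tab <- table(factor(x$pairs$fate, levels = response_fates()))
  cat("Response network:", length(x$nodes), "nodes\n")
  print(tab)
  invisible(x)
}

#' Node degree distribution of a network
#'
#' @param net an \code{mi_network}.
#' @return named integer vector: counts of nodes at each degree
#'   \eqn{0 \dots N-1} (zero-degree nodes included); total mass \eqn{N}.
#' @export
degree_histogram <- function(net) {
  ed <- network_edges(net)
  deg <- setNames(integer(length(net$nodes)), net$nodes)
  if (nrow(ed)) {
    t1 <- table(c(ed$a, ed$b))
    deg[names(t1)] <- as.integer(t1)
  }
  n <- length(net$nodes)
  tabulate(deg + 1L, nbins = n) |>
    setNames(as.character(0:(n - 1L)))
}

#' Node degrees of a network
#' @param net an \code{mi_network}.
#' @return named integer vector of per-node degrees.
#' @export
node_degrees <- function(net) {
  ed <- network_edges(net)
  deg <- setNames(integer(length(net$nodes)), net$nodes)
  if (nrow(ed)) {
    t1 <- table(c(ed$a, ed$b))
    deg[names(t1)] <- as.integer(t1)
  }
  deg
}

#' Compare the degree distributions of two networks
#'
#' Two-sample test on the per-node degree sequences. Default test is the
#' two-sample Cramér-von Mises test (consistent with the distribution
#' comparisons elsewhere in the package); Kolmogorov-Smirnov is available.
#' A Bonferroni multiplier for a family of comparisons can be applied by the
#' caller through \code{bonferroni}.
#'
#' @param netA,netB networks.
#' @param test \code{"cvm"} or \code{"ks"}.
#' @param bonferroni family-size multiplier applied to the p-value (capped
#'   at 1).
#' @return list with \code{statistic}, \code{p_value}, \code{test}.
#' @export
compare_degree_distributions <- function(netA, netB, test = c("cvm", "ks"),
                                         bonferroni = 1) {
  test <- match.arg(test)
  dA <- node_degrees(netA); dB <- node_degrees(netB)
  if (test == "cvm") {
    r <- cvm_two_sample(dA, dB)
    out <- list(statistic = r$statistic, p_value = r$p_value)
  } else {
    r <- suppressWarnings(stats::ks.test(dA, dB))
    out <- list(statistic = unname(r$statistic), p_value = r$p.value)
  }
  out$p_value <- min(1, out$p_value * bonferroni)
  out$test <- test
  out
}
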
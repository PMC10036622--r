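# Shared fixtures built in code.

# Independent Cox-de Boor recursion: the oracle for bspline_weights().
# Order-k basis function i over the given knot vector, evaluated at x.
cox_de_boor <- function(x, i, k, knots) {
  if (k == 1L) {
    return(as.numeric(knots[i] <= x & x < knots[i + 1L]))
  }
  d1 <- knots[i + k - 1L] - knots[i]
  d2 <- knots[i + k] - knots[i + 1L]
  t1 <- if (d1 > 0) (x - knots[i]) / d1 * cox_de_boor(x, i, k - 1L, knots)
        else 0
  t2 <- if (d2 > 0) (knots[i + k] - x) / d2 *
          cox_de_boor(x, i + 1L, k - 1L, knots) else 0
  t1 + t2
}

# The knot vector bspline_weights() uses for (k, M).
bspline_knots <- function(k, M) c(rep(0, k), seq_len(M - k), rep(M - k + 1, k))

# Closed-form discrete MI of a joint probability table (nats).
discrete_mi <- function(joint) {
  px <- rowSums(joint); py <- colSums(joint)
  total <- 0
  for (i in seq_len(nrow(joint))) for (j in seq_len(ncol(joint))) {
    if (joint[i, j] > 0)
      total <- total + joint[i, j] * log(joint[i, j] / (px[i] * py[j]))
  }
  as.numeric(total)
}

# Direct ECDF-sum evaluation of the two-sample Cramér-von Mises statistic:
# T = nm/(n+m)^2 * sum over pooled observations of (F_n - G_m)^2.
cvm_brute_force <- function(a, b) {
  pooled <- c(a, b)
  Fa <- ecdf(a)(pooled)
  Gb <- ecdf(b)(pooled)
  length(a) * length(b) / (length(a) + length(b))^2 * sum((Fa - Gb)^2)
}

# Minimal hand-built network over given nodes and edge pairs (p = 0 for
# edges, p = 1 otherwise), for tests that need exact edge control.
toy_network <- function(nodes, edge_pairs, p0 = 0.05) {
  cmb <- t(combn(nodes, 2L))
  pairs <- data.frame(a = cmb[, 1L], b = cmb[, 2L], mi = 0, p = 1,
                      M = 3L, stringsAsFactors = FALSE)
  for (e in edge_pairs) {
    hit <- (pairs$a == e[1] & pairs$b == e[2]) |
           (pairs$a == e[2] & pairs$b == e[1])
    pairs$p[hit] <- 0
    pairs$mi[hit] <- 1
  }
  structure(list(nodes = nodes, pairs = pairs, p0 = p0,
                 excluded = character(), config = mi_config()),
            class = "mi_network")
}

# Small annotated fixture: 2 A-nodes, 2 C-nodes with single labels.
toy_annotations <- function() {
  list(n1 = "A", n2 = "A", n3 = "C", n4 = "C")
}
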
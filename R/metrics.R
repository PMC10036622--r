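#' Graph density
#'
#' \eqn{D = 2E / (N(N-1))}: realized edges over the full-connection count.
#'
#' @param E number of edges (may be a weighted, non-integer count).
#' @param N number of nodes, \eqn{N \ge 2}.
#' @return density in \eqn{[0, 1]}.
#' @export
graph_density <- function(E, N) {
  if (any(N < 2)) stop("N must be >= 2")
  if (any(E < 0) || any(E > full_connection_count(N)))
    stop("E must lie in [0, N(N-1)/2]")
  2 * E / (N * (N - 1))
}

#' Per-edge-type graph density
#'
#' For each ET, \eqn{D_{ET} = 2 E_{ET} / (N_{ET}(N_{ET}-1))}, where
#' \eqn{E_{ET}} is the weighted count of edges carrying that ET and
#' \eqn{N_{ET}} is the number of nodes whose label set intersects the ET's
#' label pair (so the denominator of a cross-type ET also includes same-type
#' pairs, exactly as the formula is stated; a tighter bipartite denominator
#' \eqn{N_a N_b} is available via \code{bipartite = TRUE}). ETs with
#' \eqn{N_{ET} < 2} have undefined density, reported as \code{NA}.
#'
#' @param edges edge data frame (\code{a}, \code{b}) or an
#'   \code{mi_network}.
#' @param annotations named list: molecule ID -> labels.
#' @param catalog an \code{et_catalog}.
#' @param nodes node IDs of the graph (required when \code{edges} is a plain
#'   data frame).
#' @param bipartite use \eqn{N_a N_b} as the cross-type denominator.
#' @return data frame per catalog ET: \code{et}, \code{N_ET}, \code{E_ET},
#'   \code{D_ET}.
#' @export
et_graph_density <- function(edges, annotations, catalog, nodes = NULL,
                             bipartite = FALSE) {
  if (inherits(edges, "mi_network")) {
    nodes <- edges$nodes
    edges <- network_edges(edges)
  }
  if (is.null(nodes)) stop("nodes required when edges is a data frame")
  dist <- et_distribution(edges, annotations, catalog)
  labels_of <- function(id) annotations[[id]] %||% character()
  node_labels <- lapply(nodes, labels_of)
  out <- catalog[, c("et", "label_a", "label_b"), drop = FALSE]
  out$E_ET <- as.numeric(dist[catalog$et])
  n_with <- function(lab) sum(vapply(node_labels, function(x) lab %in% x,
                                     logical(1)))
  out$N_ET <- mapply(function(la, lb) {
    if (la == lb) n_with(la)
    else sum(vapply(node_labels, function(x) any(c(la, lb) %in% x),
                    logical(1)))
  }, catalog$label_a, catalog$label_b)
  denom <- if (bipartite) {
    mapply(function(la, lb) {
      if (la == lb) full_connection_count(max(n_with(la), 1))
      else n_with(la) * n_with(lb)
    }, catalog$label_a, catalog$label_b)
  } else {
    ifelse(out$N_ET >= 2, full_connection_count(pmax(out$N_ET, 1)), NA_real_)
  }
  out$D_ET <- ifelse(!is.na(denom) & denom > 0, out$E_ET / denom, NA_real_)
  rownames(out) <- NULL
  out[, c("et", "N_ET", "E_ET", "D_ET")]
}

#' Conventional per-node network statistics
#'
#' Standard descriptors computed on the present-edge graph: per-node mean
#' shortest-path length (over reachable pairs only; isolated nodes
#' \code{NA}), local clustering coefficient, degree centrality (degree /
#' (N-1)), closeness centrality (isolated nodes 0) and betweenness
#' centrality. Graph-level means are attached as the \code{"means"}
#' attribute (characteristic path length = mean of the per-node path means).
#'
#' @param net an \code{mi_network}.
#' @return data frame with one row per node and columns \code{path_mean},
#'   \code{clustering}, \code{degree_cent}, \code{closeness_cent},
#'   \code{betweenness_cent}.
#' @export
conventional_stats <- function(net) {
  g <- as_igraph(net)
  n <- igraph::vcount(g)
  d <- igraph::distances(g)
  diag(d) <- NA
  d[is.infinite(d)] <- NA
  path_mean <- rowMeans(d, na.rm = TRUE)
  path_mean[!is.finite(path_mean)] <- NA
  clustering <- igraph::transitivity(g, type = "local", isolates = "zero")
  deg <- igraph::degree(g)
  degree_cent <- deg / (n - 1)
  closeness_cent <- rep(0, n)
  pos <- deg > 0
  if (any(pos)) {
    cl <- suppressWarnings(igraph::closeness(g, vids = which(pos),
                                             normalized = TRUE))
    closeness_cent[pos] <- cl
  }
  betweenness_cent <- igraph::betweenness(g, directed = FALSE)
  out <- data.frame(node = igraph::V(g)$name, path_mean = path_mean,
                    clustering = clustering, degree_cent = degree_cent,
                    closeness_cent = closeness_cent,
                    betweenness_cent = betweenness_cent,
                    stringsAsFactors = FALSE)
  attr(out, "means") <- c(
    characteristic_path_length = mean(path_mean, na.rm = TRUE),
    clustering = mean(clustering, na.rm = TRUE),
    degree_cent = mean(degree_cent),
    closeness_cent = mean(closeness_cent),
    betweenness_cent = mean(betweenness_cent))
  out
}

# Absolute Spearman correlation with pairwise-complete observations;
# NA when either vector is constant (correlation undefined).
abs_spearman <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 2L || sd(x[ok]) == 0 || sd(y[ok]) == 0) return(NA_real_)
  abs(cor(x[ok], y[ok], method = "spearman"))
}

scan_stat_names <- function() {
  c("et_density", "path_mean", "clustering", "degree_cent",
    "closeness_cent", "betweenness_cent")
}

# Statistic vectors of one network at its current threshold.
scan_vectors <- function(net, annotations, catalog) {
  cs <- conventional_stats(net)
  list(et_density = et_graph_density(net, annotations, catalog)$D_ET,
       path_mean = cs$path_mean,
       clustering = cs$clustering,
       degree_cent = cs$degree_cent,
       closeness_cent = cs$closeness_cent,
       betweenness_cent = cs$betweenness_cent)
}

#' Threshold-robustness scan
#'
#' Rebuilds the network at each p-value threshold from the stored per-pair
#' p-values (no re-permutation) and measures, for the per-ET graph-density
#' vector and each conventional per-node statistic vector, the absolute
#' Spearman rank correlation against the corresponding vector at the
#' reference threshold. Each curve is normalized so its value at the
#' reference is 1; a statistic whose reference vector is constant yields
#' \code{NA}.
#'
#' @param net an \code{mi_network} holding all pairwise p-values.
#' @param thresholds numeric vector of thresholds; must contain
#'   \code{reference}.
#' @param annotations named list: molecule ID -> labels.
#' @param catalog an \code{et_catalog}.
#' @param reference reference threshold (default 0.05).
#' @return data frame: \code{threshold} plus one column per statistic.
#' @export
robustness_scan <- function(net, thresholds, annotations, catalog,
                            reference = 0.05) {
  if (!any(abs(thresholds - reference) < 1e-12))
    stop("thresholds must include the reference")
  vecs <- lapply(thresholds, function(th)
    scan_vectors(set_threshold(net, th), annotations, catalog))
  ref <- vecs[[which.min(abs(thresholds - reference))]]
  scan_correlations(vecs, ref, thresholds, "threshold")
}

#' Cross-condition statistic scan
#'
#' Same statistics as \code{\link{robustness_scan}}, but correlating each
#' condition's network against a reference condition's network (all at their
#' own fixed threshold), normalized to 1 at the reference.
#'
#' @param networks named list of \code{mi_network}s over a common node set.
#' @param reference name of the reference condition.
#' @param annotations named list: molecule ID -> labels.
#' @param catalog an \code{et_catalog}.
#' @return data frame: \code{condition} plus one column per statistic.
#' @export
condition_scan <- function(networks, reference, annotations, catalog) {
  if (!reference %in% names(networks)) stop("unknown reference condition")
  vecs <- lapply(networks, scan_vectors, annotations = annotations,
                 catalog = catalog)
  scan_correlations(vecs, vecs[[reference]], names(networks), "condition")
}

scan_correlations <- function(vecs, ref, index, index_name) {
  stats <- scan_stat_names()
  rows <- lapply(vecs, function(v)
    vapply(stats, function(s) abs_spearman(v[[s]], ref[[s]]), numeric(1)))
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- stats
  # self-correlation is exactly 1, so normalization leaves curves unchanged;
  # kept explicit for the contract "reference value equals 1"
  ref_row <- vapply(stats, function(s) abs_spearman(ref[[s]], ref[[s]]),
                    numeric(1))
  for (s in stats) out[[s]] <- out[[s]] / ref_row[[s]]
  cbind(setNames(data.frame(index, stringsAsFactors = FALSE), index_name),
        out, row.names = NULL)
}
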
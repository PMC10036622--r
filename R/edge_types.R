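#' The 11 KEGG "Metabolism" node-type classes
#'
#' The default node-type scheme: the eleven top-level classes of metabolism
#' in the KEGG PATHWAY database, in catalog order.
#'
#' @return character vector of 11 labels.
#' @export
kegg_metabolism_classes <- function() {
  c("Carbohydrate metabolism",
    "Energy metabolism",
    "Lipid metabolism",
    "Nucleotide metabolism",
    "Amino acid metabolism",
    "Metabolism of other amino acids",
    "Glycan biosynthesis and metabolism",
    "Metabolism of cofactors and vitamins",
    "Metabolism of terpenoids and polyketides",
    "Biosynthesis of other secondary metabolites",
    "Xenobiotics biodegradation and metabolism")
}

#' Edge-type catalog for a node-type scheme
#'
#' All unordered pairs of the \eqn{s} labels including same-label pairs:
#' \eqn{t = s(s-1)/2 + s} edge types, ordered lexicographically by label
#' indices in the scheme.
#'
#' @param scheme ordered character vector of unique node-type labels.
#' @return an object of class \code{et_catalog}: data frame with columns
#'   \code{no} (1-based ET number), \code{et} (ID string
#'   \code{"labelA--labelB"}), \code{label_a}, \code{label_b}; attribute
#'   \code{"scheme"}.
#' @export
build_catalog <- function(scheme) {
  scheme <- as.character(scheme)
  if (length(scheme) < 1L || anyDuplicated(scheme) || any(!nzchar(scheme)))
    stop("scheme labels must be unique and nonempty")
  s <- length(scheme)
  ia <- rep(seq_len(s), times = s - seq_len(s) + 1L)
  ib <- unlist(lapply(seq_len(s), function(i) seq.int(i, s)))
  cat_df <- data.frame(no = seq_along(ia),
                       et = paste(scheme[ia], scheme[ib], sep = "--"),
                       label_a = scheme[ia], label_b = scheme[ib],
                       stringsAsFactors = FALSE)
  structure(cat_df, scheme = scheme, class = c("et_catalog", "data.frame"))
}

# Canonical ET id for two labels under a scheme ordering.
et_id <- function(la, lb, scheme) {
  ia <- match(la, scheme); ib <- match(lb, scheme)
  swap <- ib < ia
  paste(scheme[ifelse(swap, ib, ia)], scheme[ifelse(swap, ia, ib)],
        sep = "--")
}

#' Restrict a catalog to a subset of labels
#'
#' Keeps the edge types whose both labels are in \code{labels}, reordered by
#' the ordering of \code{labels} (e.g. the 15 ETs over the five major
#' metabolite classes, numbered alphabetically by initial).
#'
#' @param catalog an \code{et_catalog}.
#' @param labels labels to keep, in the desired order.
#' @return a new \code{et_catalog} over \code{labels}.
#' @export
subset_catalog <- function(catalog, labels) {
  if (!all(labels %in% attr(catalog, "scheme")))
    stop("labels not all in the catalog's scheme")
  build_catalog(labels)
}

#' Edge types of one edge, with fractional multi-label weights
#'
#' The ET set of an edge is formed by all pairwise combinations of the two
#' endpoints' label sets, collapsed to distinct unordered label pairs; each
#' distinct ET receives equal weight \eqn{1 / \#E_{type}} so every typed
#' edge contributes total weight exactly 1.
#'
#' @param id_a,id_b endpoint molecule IDs.
#' @param annotations named list: molecule ID -> character vector of labels.
#' @param catalog an \code{et_catalog}.
#' @return named numeric vector of weights over ET IDs (summing to 1), or
#'   \code{NULL} if either endpoint is unannotated (the edge is untyped).
#' @export
edge_types_of <- function(id_a, id_b, annotations, catalog) {
  la <- annotations[[id_a]]; lb <- annotations[[id_b]]
  if (is.null(la) || is.null(lb) || !length(la) || !length(lb)) return(NULL)
  scheme <- attr(catalog, "scheme")
  if (!all(c(la, lb) %in% scheme)) stop("label outside the catalog scheme")
  combos <- expand.grid(a = la, b = lb, stringsAsFactors = FALSE)
  ets <- unique(et_id(combos$a, combos$b, scheme))
  setNames(rep(1 / length(ets), length(ets)), ets)
}

#' Weighted edge-type distribution of an edge set
#'
#' Counts the appearance of each ET over a set of edges, each edge spreading
#' unit weight over its (distinct) ETs. Edges with an unannotated endpoint
#' are excluded from the counts and reported in the \code{"untyped"}
#' attribute. The total weight equals the number of typed edges.
#'
#' @param edges data frame with columns \code{a}, \code{b} (e.g. from
#'   \code{\link{network_edges}}), or an \code{mi_network}.
#' @param annotations named list: molecule ID -> labels.
#' @param catalog an \code{et_catalog}.
#' @return named numeric vector over the full catalog (class
#'   \code{et_distribution}); attribute \code{"untyped"} = number of
#'   excluded edges.
#' @export
et_distribution <- function(edges, annotations, catalog) {
  if (inherits(edges, "mi_network")) edges <- network_edges(edges)
  out <- setNames(numeric(nrow(catalog)), catalog$et)
  untyped <- 0L
  for (r in seq_len(nrow(edges))) {
    w <- edge_types_of(edges$a[r], edges$b[r], annotations, catalog)
    if (is.null(w)) untyped <- untyped + 1L
    else out[names(w)] <- out[names(w)] + w
  }
  structure(out, untyped = untyped, class = "et_distribution")
}

#' Per-ET histograms of response-edge fates
#'
#' For every edge type, the weighted count of node pairs in each of the four
#' fates (\code{PtoP}, \code{AtoP}, \code{PtoA}, \code{AtoA}). All pairs of
#' the response network are typed with the same fractional weighting as
#' present edges, so the grand total equals the number of typed pairs.
#'
#' @param resp a \code{\link{response_network}}.
#' @param annotations named list: molecule ID -> labels.
#' @param catalog an \code{et_catalog}.
#' @return numeric matrix, rows = catalog ETs, columns = the four fates;
#'   attribute \code{"untyped"} = number of pairs with an unannotated
#'   endpoint.
#' @export
response_distribution_per_et <- function(resp, annotations, catalog) {
  stopifnot(inherits(resp, "response_network"))
  fates <- response_fates()
  out <- matrix(0, nrow = nrow(catalog), ncol = length(fates),
                dimnames = list(catalog$et, fates))
  untyped <- 0L
  pr <- resp$pairs
  for (r in seq_len(nrow(pr))) {
    w <- edge_types_of(pr$a[r], pr$b[r], annotations, catalog)
    if (is.null(w)) untyped <- untyped + 1L
    else out[names(w), pr$fate[r]] <- out[names(w), pr$fate[r]] + w
  }
  structure(out, untyped = untyped)
}

#' Write an ET distribution as TSV (with JSON mirror)
#'
#' @param dist an \code{et_distribution}.
#' @param catalog the catalog it was computed against.
#' @param path output TSV path; a \code{.json} mirror is written alongside.
#' @export
write_et_distribution <- function(dist, catalog, path) {
  df <- data.frame(et_id = catalog$no, label_pair = catalog$et,
                   weight = as.numeric(dist), stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(setNames(as.list(as.numeric(dist)), catalog$et),
                       sub("\\.tsv$", ".json", path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
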
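#' Read and write molecule-by-sample abundance matrices
#'
#' TSV layout: header row of sample IDs; first column \code{molecule_id};
#' one row per molecule.
#'
#' @param path file path.
#' @return numeric matrix with molecule IDs as rownames.
#' @export
read_matrix_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df[[1L]])) stop("duplicate molecule IDs in ", path)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- as.character(df[[1L]])
  storage.mode(mat) <- "double"
  mat
}

#' @rdname read_matrix_tsv
#' @param mat numeric matrix, molecules in rows.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(molecule_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write multi-label node annotations
#'
#' TSV layout: \code{molecule_id <tab> labels}, labels pipe-separated.
#'
#' @param path file path.
#' @return named list: molecule ID -> character vector of labels.
#' @export
read_annotations_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  out <- strsplit(as.character(df[[2L]]), "|", fixed = TRUE)
  names(out) <- as.character(df[[1L]])
  out
}

#' @rdname read_annotations_tsv
#' @param annotations named list: molecule ID -> labels.
#' @export
write_annotations_tsv <- function(annotations, path) {
  df <- data.frame(molecule_id = names(annotations),
                   labels = vapply(annotations, paste, "", collapse = "|"),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a network's edges
#'
#' Writes the present edges of an inferred network as an edge-list TSV
#' (\code{molecule_a, molecule_b, mi_nats, p_value, M_used}), a SIF file, or
#' GraphML (via igraph) with MI/p-value edge attributes and node-type node
#' attributes when annotations are supplied.
#'
#' @param net an \code{mi_network}.
#' @param path output file.
#' @param format \code{"tsv"}, \code{"sif"} or \code{"graphml"}.
#' @param annotations optional named list of node labels (GraphML only).
#' @export
export_network <- function(net, path, format = c("tsv", "sif", "graphml"),
                           annotations = NULL) {
  format <- match.arg(format)
  ed <- network_edges(net)
  if (format == "tsv") {
    write.table(ed[, c("a", "b", "mi", "p", "M")], path, sep = "\t",
                quote = FALSE, row.names = FALSE,
                col.names = c("molecule_a", "molecule_b", "mi_nats",
                              "p_value", "M_used"))
  } else if (format == "sif") {
    writeLines(paste(ed$a, "mi", ed$b), path)
  } else {
    g <- as_igraph(net)
    if (!is.null(annotations)) {
      igraph::V(g)$node_types <- vapply(
        annotations[igraph::V(g)$name],
        function(x) paste(x %||% character(), collapse = "|"), "")
    }
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Convert an inferred network to an igraph object
#'
#' Present edges carry \code{mi} and \code{p} attributes; all (non-excluded)
#' nodes are kept, including isolated ones.
#'
#' @param net an \code{mi_network}.
#' @return an igraph undirected graph.
#' @export
as_igraph <- function(net) {
  ed <- network_edges(net)
  igraph::graph_from_data_frame(ed[, c("a", "b", "mi", "p")],
                                directed = FALSE,
                                vertices = data.frame(name = net$nodes))
}
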
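#' Build an interaction network from an edge data frame
#'
#' Internal constructor shared by the STRING reader and the synthetic
#' generator. Enforces the network invariants: undirected, simple (no
#' self-loops, no duplicate unordered pairs), confidences in [0, 1], and a
#' deterministic lexicographic node order.
#'
#' @param edges Data frame with columns `node_a`, `node_b`, `confidence`.
#' @param nodes Optional character vector of node names to include even when
#'   isolated (i.e. absent from `edges`).
#' @param min_confidence Confidence threshold recorded in the network
#'   metadata (edges are assumed already filtered).
#' @param source Free-text label recorded in the network metadata.
#' @return An [igraph::igraph] object with edge attribute `confidence` and
#'   graph attributes `min_confidence` and `source`. The confidence is kept
#'   out of the `weight` attribute on purpose: all topological computations
#'   are unweighted.
#' @export
make_network <- function(edges, nodes = NULL, min_confidence = 0,
                         source = "user") {
  stopifnot(all(c("node_a", "node_b", "confidence") %in% names(edges)))
  edges <- edges[edges$node_a != edges$node_b, , drop = FALSE]
  # canonical unordered pair; keep max confidence across duplicates
  a <- pmin(edges$node_a, edges$node_b)
  b <- pmax(edges$node_a, edges$node_b)
  key <- paste(a, b, sep = "\r")
  ord <- order(key, -edges$confidence)
  first <- !duplicated(key[ord])
  canon <- data.frame(node_a = a[ord][first], node_b = b[ord][first],
                      confidence = edges$confidence[ord][first],
                      stringsAsFactors = FALSE)
  all_nodes <- sort(unique(c(canon$node_a, canon$node_b, nodes)))
  g <- igraph::graph_from_data_frame(canon, directed = FALSE,
                                     vertices = all_nodes)
  g <- igraph::set_graph_attr(g, "min_confidence", min_confidence)
  igraph::set_graph_attr(g, "source", source)
}

#' Read a STRING-style edge list
#'
#' Parses a whitespace- or tab-delimited edge list in the STRING export
#' dialect (`protein1 protein2 combined_score`, score an integer on the
#' 0-1000 scale), normalizes scores to [0, 1], drops edges below the
#' confidence threshold, merges reciprocal duplicates keeping the maximum
#' confidence, and drops self-loops with a counted warning.
#'
#' @param path Path to the edge-list file (header row expected).
#' @param min_confidence Minimum normalized confidence in [0, 1]; edges with
#'   `combined_score/1000 < min_confidence` are dropped. Default 0.4, the
#'   STRING "medium confidence" convention.
#' @param aliases Optional data frame (or path to a two-column headerless
#'   TSV) mapping STRING identifiers to gene symbols; first column the
#'   identifier, second the symbol.
#' @return An interaction network (see [make_network()]).
#' @export
read_string_edges <- function(path, min_confidence = 0.4, aliases = NULL) {
  if (min_confidence < 0 || min_confidence > 1) {
    stop("`min_confidence` must lie in [0, 1]", call. = FALSE)
  }
  raw <- utils::read.table(path, header = TRUE, sep = "",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", comment.char = "",
                           fileEncoding = "UTF-8")
  cols <- c("protein1", "protein2", "combined_score")
  if (!all(cols %in% names(raw))) {
    if (ncol(raw) < 3) stop("edge list needs >= 3 columns", call. = FALSE)
    names(raw)[1:3] <- cols
  }
  score <- suppressWarnings(as.numeric(raw$combined_score))
  bad <- which(is.na(score) | score < 0 | score > 1000)
  if (length(bad) > 0) {
    stop("malformed combined_score in row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.null(aliases)) {
    if (is.character(aliases)) {
      aliases <- utils::read.table(aliases, header = FALSE, sep = "",
                                   stringsAsFactors = FALSE,
                                   colClasses = "character")
    }
    map <- stats::setNames(aliases[[2]], aliases[[1]])
    hit1 <- raw$protein1 %in% names(map)
    hit2 <- raw$protein2 %in% names(map)
    raw$protein1[hit1] <- map[raw$protein1[hit1]]
    raw$protein2[hit2] <- map[raw$protein2[hit2]]
  }
  n_loops <- sum(raw$protein1 == raw$protein2)
  if (n_loops > 0) {
    warning(n_loops, " self-loop(s) dropped", call. = FALSE)
  }
  conf <- score / 1000
  keep <- conf >= min_confidence & raw$protein1 != raw$protein2
  if (!any(keep)) {
    stop("empty network: no edges at or above confidence ",
         min_confidence, call. = FALSE)
  }
  make_network(
    data.frame(node_a = raw$protein1[keep], node_b = raw$protein2[keep],
               confidence = conf[keep], stringsAsFactors = FALSE),
    min_confidence = min_confidence,
    source = paste0("string:", basename(path))
  )
}

#' Write a normalized edge list
#'
#' Emits the canonical TSV dialect `node_a  node_b  confidence` with
#' confidences as 0-1 reals at 3 decimals, edges in lexicographic order.
#'
#' @param network Interaction network.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edges <- function(network, path) {
  el <- igraph::as_data_frame(network, what = "edges")
  if (nrow(el) > 0) {
    a <- pmin(el$from, el$to)
    b <- pmax(el$from, el$to)
    out <- data.frame(node_a = a, node_b = b,
                      confidence = sprintf("%.3f", el$confidence),
                      stringsAsFactors = FALSE)
    out <- out[order(out$node_a, out$node_b), , drop = FALSE]
  } else {
    out <- data.frame(node_a = character(), node_b = character(),
                      confidence = character())
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Induce the subnetwork on a node set
#'
#' Restricts the network to the given gene symbols: nodes are the
#' intersection of `node_set` with the network's nodes, plus (by default)
#' members of `node_set` absent from the network, included as isolated
#' nodes so that they still receive (worst) ranks downstream. Edges are
#' those with both endpoints in the set.
#'
#' @param network Interaction network.
#' @param node_set Non-empty character vector of gene symbols.
#' @param include_isolated Include `node_set` members missing from the
#'   network as isolated nodes (default `TRUE`).
#' @return The induced interaction network.
#' @export
induce_subnetwork <- function(network, node_set, include_isolated = TRUE) {
  if (length(node_set) == 0) {
    stop("`node_set` must be non-empty", call. = FALSE)
  }
  node_set <- unique(node_set)
  present <- intersect(node_set, igraph::V(network)$name)
  g <- igraph::induced_subgraph(network, vids = present)
  missing <- setdiff(node_set, present)
  if (include_isolated && length(missing) > 0) {
    g <- igraph::add_vertices(g, length(missing), name = missing)
  }
  g <- igraph::permute(g, match(igraph::V(g)$name, sort(igraph::V(g)$name)))
  g <- igraph::set_graph_attr(
    g, "min_confidence",
    igraph::graph_attr(network, "min_confidence"))
  igraph::set_graph_attr(g, "source", igraph::graph_attr(network, "source"))
}
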
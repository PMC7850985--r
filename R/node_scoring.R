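#' Per-node topological centralities
#'
#' Computes, for every node of a simple undirected network: degree `k`,
#' local clustering coefficient `CC` (fraction of closed triples; 0 for
#' degree < 2), betweenness centrality normalized by the number of node
#' pairs excluding the node, `(n-1)(n-2)/2`, and harmonic closeness
#' normalized by `n-1`. Harmonic closeness (the mean of reciprocal
#' distances, with unreachable pairs contributing 0) is used instead of
#' classical closeness so that disconnected graphs — and graphs after node
#' deletion — remain well-defined. All computations are unweighted.
#'
#' @param network Interaction network (see [make_network()]).
#' @return Data frame with columns `node`, `degree`, `clustering`,
#'   `betweenness`, `closeness`, one row per node in lexicographic order.
#' @export
compute_centralities <- function(network) {
  n <- igraph::vcount(network)
  stopifnot(n >= 1)
  nodes <- igraph::V(network)$name
  ord <- order(nodes)

  deg <- igraph::degree(network)
  cc <- igraph::transitivity(network, type = "local", isolates = "zero")
  btw <- if (n >= 3) {
    igraph::betweenness(network, directed = FALSE, normalized = TRUE)
  } else {
    rep(0, n)
  }
  clo <- if (n >= 2) {
    igraph::harmonic_centrality(network, normalized = TRUE)
  } else {
    rep(0, n)
  }

  data.frame(
    node        = nodes[ord],
    degree      = as.integer(deg[ord]),
    clustering  = as.numeric(cc)[ord],
    betweenness = as.numeric(btw)[ord],
    closeness   = as.numeric(clo)[ord],
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Network centrality index
#'
#' The summary statistic whose change under node deletion defines the
#' perturbation score: the mean, over nodes, of the per-node average of
#' clustering coefficient, normalized betweenness, and normalized harmonic
#' closeness. Always lies in [0, 1]; a single-node or edgeless graph
#' scores 0.
#'
#' @param network Interaction network.
#' @return A single number in [0, 1].
#' @export
network_centrality_index <- function(network) {
  ct <- compute_centralities(network)
  if (nrow(ct) == 0) return(0)
  mean((ct$clustering + ct$betweenness + ct$closeness) / 3)
}

#' Perturbation scores under single-node deletion
#'
#' For each node `v`, the perturbation score is the absolute change of the
#' [network_centrality_index()] caused by removing `v` and its edges:
#' `P(v) = |C(G) - C(G \ v)|`.
#'
#' @param network Interaction network with at least two nodes.
#' @return Named numeric vector of perturbation scores, nodes in
#'   lexicographic order.
#' @export
perturbation_scores <- function(network) {
  n <- igraph::vcount(network)
  if (n < 2) stop("perturbation requires at least 2 nodes", call. = FALSE)
  base <- network_centrality_index(network)
  nodes <- sort(igraph::V(network)$name)
  scores <- vapply(nodes, function(v) {
    abs(base - network_centrality_index(igraph::delete_vertices(network, v)))
  }, numeric(1))
  scores
}

#' Disruption scores under single-node deletion
#'
#' For each node `v`, considers every unordered pair `(u, w)` of remaining
#' nodes that is connected in the original graph, and measures how much the
#' shortest-path distance grows when `v` is deleted. Pairs severed by the
#' deletion (connected in `G`, disconnected in `G \ v`) receive the finite
#' penalty `|V| - d_G(u, w)`, i.e. their post-deletion distance is replaced
#' by `|V|`, one more than the largest possible finite distance. The
#' disruption score `D(v)` is the mean increase over those pairs (0 when no
#' eligible pair exists), and the number of severed pairs is reported
#' alongside — it is positive exactly when `v` is an articulation point.
#'
#' @param network Interaction network with at least three nodes.
#' @return Data frame with columns `node`, `disruption`, `severed_pairs`,
#'   nodes in lexicographic order.
#' @export
disruption_scores <- function(network) {
  n <- igraph::vcount(network)
  if (n < 3) stop("disruption requires at least 3 nodes", call. = FALSE)
  nodes <- sort(igraph::V(network)$name)
  d0 <- igraph::distances(network)
  d0 <- d0[nodes, nodes, drop = FALSE]

  res <- lapply(nodes, function(v) {
    others <- setdiff(nodes, v)
    g_del <- igraph::delete_vertices(network, v)
    d1 <- igraph::distances(g_del)[others, others, drop = FALSE]
    base <- d0[others, others, drop = FALSE]
    ut <- upper.tri(base)
    connected <- is.finite(base) & ut
    m <- sum(connected)
    if (m == 0) return(c(disruption = 0, severed_pairs = 0))
    severed <- connected & !is.finite(d1)
    inc <- d1 - base
    inc[severed] <- n - base[severed]
    c(disruption = sum(inc[connected]) / m,
      severed_pairs = sum(severed))
  })
  out <- do.call(rbind, res)
  data.frame(
    node = nodes,
    disruption = as.numeric(out[, "disruption"]),
    severed_pairs = as.integer(out[, "severed_pairs"]),
    stringsAsFactors = FALSE
  )
}

#' Full per-node score table
#'
#' Combines [compute_centralities()], [perturbation_scores()] and
#' [disruption_scores()] into the per-node score table used for ranking.
#'
#' @param network Interaction network with at least three nodes.
#' @return Data frame with columns `node`, `degree`, `clustering`,
#'   `betweenness`, `closeness`, `perturbation`, `disruption`,
#'   `severed_pairs`, one row per node in lexicographic order.
#' @export
score_nodes <- function(network) {
  ct <- compute_centralities(network)
  ct$perturbation <- as.numeric(perturbation_scores(network))
  dis <- disruption_scores(network)
  stopifnot(identical(ct$node, dis$node))
  ct$disruption <- dis$disruption
  ct$severed_pairs <- dis$severed_pairs
  ct
}

#' Write a per-node score table
#'
#' TSV with reals at 6 decimals, nodes in lexicographic order.
#'
#' @param scores Data frame from [score_nodes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(scores, path) {
  out <- scores
  for (col in c("clustering", "betweenness", "closeness",
                "perturbation", "disruption")) {
    out[[col]] <- sprintf("%.6f", out[[col]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
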
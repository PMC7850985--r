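# Brute-force reference implementations used to cross-check the fast path.
# They share nothing with the igraph-based computations beyond reading the
# edge list out of the network container: distances come from a hand-rolled
# BFS, betweenness from explicit enumeration of all simple paths. Intended
# for small graphs (|V| <= ~10) in tests.

adjacency_list <- function(network) {
  nodes <- sort(igraph::V(network)$name)
  el <- igraph::as_data_frame(network, what = "edges")
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (v in nodes) adj[[v]] <- character(0)
  if (nrow(el) > 0) {
    for (i in seq_len(nrow(el))) {
      a <- el$from[i]; b <- el$to[i]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  lapply(adj, sort)
}

#' All-pairs shortest-path distances by breadth-first search
#'
#' Reference distance oracle: plain BFS from every node, unweighted.
#' Unreachable pairs carry the `Inf` sentinel.
#'
#' @param network Interaction network.
#' @return Numeric matrix of distances, rows/columns named by node in
#'   lexicographic order.
#' @export
oracle_all_pairs <- function(network) {
  adj <- adjacency_list(network)
  nodes <- names(adj)
  n <- length(nodes)
  d <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  for (s in nodes) {
    dist <- stats::setNames(rep(Inf, n), nodes)
    dist[s] <- 0
    frontier <- s
    while (length(frontier) > 0) {
      nxt <- character(0)
      for (u in frontier) {
        for (w in adj[[u]]) {
          if (!is.finite(dist[w])) {
            dist[w] <- dist[u] + 1
            nxt <- c(nxt, w)
          }
        }
      }
      frontier <- nxt
    }
    d[s, ] <- dist[nodes]
  }
  d
}

# enumerate all simple paths from `from` to `to`; returns list of character
# vectors (inclusive of endpoints)
simple_paths <- function(adj, from, to) {
  paths <- list()
  walk <- function(path) {
    tail <- path[length(path)]
    if (tail == to) {
      paths[[length(paths) + 1L]] <<- path
      return(invisible())
    }
    for (w in adj[[tail]]) {
      if (!(w %in% path)) walk(c(path, w))
    }
  }
  walk(from)
  paths
}

#' Brute-force centralities by exhaustive path enumeration
#'
#' Computes the same quantities as [compute_centralities()] without any
#' graph-library algorithm: clustering by direct triangle counting,
#' betweenness by enumerating every simple path between every pair and
#' keeping the geodesics, harmonic closeness from the BFS distance matrix.
#'
#' @param network Interaction network (small; cost grows factorially).
#' @return Data frame matching the layout of [compute_centralities()].
#' @export
oracle_centralities <- function(network) {
  adj <- adjacency_list(network)
  nodes <- names(adj)
  n <- length(nodes)
  d <- oracle_all_pairs(network)

  deg <- vapply(adj, length, integer(1))

  cc <- vapply(nodes, function(v) {
    nb <- adj[[v]]
    k <- length(nb)
    if (k < 2) return(0)
    links <- 0L
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        if (nb[j] %in% adj[[nb[i]]]) links <- links + 1L
      }
    }
    2 * links / (k * (k - 1))
  }, numeric(1))

  btw <- stats::setNames(rep(0, n), nodes)
  if (n >= 3) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        s <- nodes[i]; t <- nodes[j]
        if (!is.finite(d[s, t])) next
        paths <- simple_paths(adj, s, t)
        lens <- vapply(paths, length, integer(1)) - 1L
        geo <- paths[lens == d[s, t]]
        sigma <- length(geo)
        for (p in geo) {
          inner <- setdiff(p, c(s, t))
          for (v in inner) btw[v] <- btw[v] + 1 / sigma
        }
      }
    }
    btw <- btw / ((n - 1) * (n - 2) / 2)
  }

  clo <- vapply(nodes, function(v) {
    if (n < 2) return(0)
    dv <- d[v, setdiff(nodes, v)]
    sum(ifelse(is.finite(dv), 1 / dv, 0)) / (n - 1)
  }, numeric(1))

  data.frame(node = nodes, degree = as.integer(deg),
             clustering = as.numeric(cc), betweenness = as.numeric(btw),
             closeness = as.numeric(clo), stringsAsFactors = FALSE,
             row.names = NULL)
}

oracle_index <- function(network) {
  ct <- oracle_centralities(network)
  if (nrow(ct) == 0) return(0)
  mean((ct$clustering + ct$betweenness + ct$closeness) / 3)
}

#' Brute-force perturbation scores
#'
#' Recomputes the centrality index from scratch (via
#' [oracle_centralities()]) for the graph and for every single-node
#' deletion; the definition itself, with no shortcuts.
#'
#' @param network Interaction network (small).
#' @return Named numeric vector, nodes in lexicographic order.
#' @export
oracle_perturbation <- function(network) {
  base <- oracle_index(network)
  nodes <- sort(igraph::V(network)$name)
  vapply(nodes, function(v) {
    abs(base - oracle_index(igraph::delete_vertices(network, v)))
  }, numeric(1))
}

#' Brute-force disruption scores
#'
#' Recomputes BFS distance matrices before and after every single-node
#' deletion and averages the pairwise increases, with the `|V|` penalty for
#' severed pairs.
#'
#' @param network Interaction network (small, at least 3 nodes).
#' @return Data frame with columns `node`, `disruption`, `severed_pairs`.
#' @export
oracle_disruption <- function(network) {
  nodes <- sort(igraph::V(network)$name)
  n <- length(nodes)
  stopifnot(n >= 3)
  d0 <- oracle_all_pairs(network)
  rows <- lapply(nodes, function(v) {
    others <- setdiff(nodes, v)
    d1 <- oracle_all_pairs(igraph::delete_vertices(network, v))
    total <- 0; m <- 0L; severed <- 0L
    for (i in seq_len(length(others) - 1)) {
      for (j in seq(i + 1, length(others))) {
        u <- others[i]; w <- others[j]
        if (!is.finite(d0[u, w])) next
        m <- m + 1L
        if (is.finite(d1[u, w])) {
          total <- total + (d1[u, w] - d0[u, w])
        } else {
          severed <- severed + 1L
          total <- total + (n - d0[u, w])
        }
      }
    }
    data.frame(node = v, disruption = if (m == 0) 0 else total / m,
               severed_pairs = severed, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
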
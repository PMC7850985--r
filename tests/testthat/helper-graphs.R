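# small-graph builders shared across tests

net_from_pairs <- function(..., nodes = NULL, confidence = 0.9) {
  pairs <- list(...)
  if (length(pairs) == 0) {
    edges <- data.frame(node_a = character(), node_b = character(),
                        confidence = numeric())
  } else {
    edges <- data.frame(
      node_a = vapply(pairs, `[`, character(1), 1),
      node_b = vapply(pairs, `[`, character(1), 2),
      confidence = confidence,
      stringsAsFactors = FALSE
    )
  }
  make_network(edges, nodes = nodes)
}

complete_net <- function(n) {
  syms <- LETTERS[seq_len(n)]
  pairs <- utils::combn(syms, 2)
  edges <- data.frame(node_a = pairs[1, ], node_b = pairs[2, ],
                      confidence = 0.9, stringsAsFactors = FALSE)
  make_network(edges)
}

star_net <- function(n_leaves) {
  leaves <- paste0("L", seq_len(n_leaves))
  make_network(data.frame(node_a = "C", node_b = leaves, confidence = 0.9,
                          stringsAsFactors = FALSE))
}

# seeded small random graph for oracle-equivalence sweeps; guarantees at
# least one edge so deletion scores are non-degenerate
random_small_net <- function(seed) {
  set.seed(seed)
  n <- sample(3:8, 1)
  p <- stats::runif(1, 0.2, 0.8)
  syms <- sprintf("N%02d", seq_len(n))
  pairs <- utils::combn(syms, 2)
  keep <- stats::runif(ncol(pairs)) < p
  if (!any(keep)) keep[sample.int(ncol(pairs), 1)] <- TRUE
  edges <- data.frame(node_a = pairs[1, keep], node_b = pairs[2, keep],
                      confidence = 0.9, stringsAsFactors = FALSE)
  make_network(edges, nodes = syms)
}

write_id_table <- function(records, path = tempfile(fileext = ".tsv")) {
  write_identifications(records, path)
  path
}
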
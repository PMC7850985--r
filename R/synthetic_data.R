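# Seeded generators emulating the three pipeline inputs: a heavy-tailed PPI
# network (optionally with a planted hub), a protein identification table
# with a controlled pass fraction, and boolean annotation tables with stated
# prevalences. Node identifiers follow the synthetic gene-symbol scheme
# G0001, G0002, ...

synthetic_symbols <- function(n) sprintf("G%04d", seq_len(n))

#' Generate a synthetic interaction network
#'
#' Topologies: `"preferential_attachment"` (Barabási–Albert; the default
#' stand-in for PPI networks, whose degree distributions are heavy-tailed),
#' `"erdos_renyi"` (G(n, p)) and `"ring_lattice"` (a cycle) for symmetric /
#' degenerate oracle cases. A hub can be planted by wiring one designated
#' node — the last one — to a stated fraction of all other nodes after the
#' base topology is laid down. Edge confidences are sampled uniformly on
#' [0.4, 1.0] (all at or above the default STRING-style inclusion
#' threshold). Identical arguments and seed give an identical graph.
#'
#' @param n_nodes Number of nodes.
#' @param topology One of `"preferential_attachment"`, `"erdos_renyi"`,
#'   `"ring_lattice"`.
#' @param attachment_edges Edges added per step (preferential attachment).
#' @param edge_probability Edge probability (Erdős–Rényi).
#' @param planted_hub Optional fraction in (0, 1]: the designated hub is
#'   connected to `ceiling(planted_hub * (n_nodes - 1))` distinct other
#'   nodes (on top of any base-topology edges it already has).
#' @param seed Integer seed; fully determines the output.
#' @return An interaction network; when a hub is planted its symbol is
#'   stored in the graph attribute `planted_hub`.
#' @export
generate_network <- function(n_nodes,
                             topology = c("preferential_attachment",
                                          "erdos_renyi", "ring_lattice"),
                             attachment_edges = 2,
                             edge_probability = NULL,
                             planted_hub = NULL,
                             seed = 1L) {
  topology <- match.arg(topology)
  if (n_nodes < 1) stop("`n_nodes` must be positive", call. = FALSE)
  if (!is.null(planted_hub) &&
      (planted_hub <= 0 || planted_hub > 1)) {
    stop("`planted_hub` must lie in (0, 1]", call. = FALSE)
  }
  set.seed(as.integer(seed))
  symbols <- synthetic_symbols(n_nodes)

  g <- switch(topology,
    preferential_attachment = {
      if (attachment_edges < 1) {
        stop("`attachment_edges` must be >= 1", call. = FALSE)
      }
      igraph::sample_pa(n_nodes, m = attachment_edges, directed = FALSE)
    },
    erdos_renyi = {
      if (is.null(edge_probability) || edge_probability < 0 ||
          edge_probability > 1) {
        stop("`edge_probability` must lie in [0, 1]", call. = FALSE)
      }
      igraph::sample_gnp(n_nodes, p = edge_probability)
    },
    ring_lattice = {
      igraph::make_ring(n_nodes)
    }
  )
  igraph::V(g)$name <- symbols
  el <- igraph::as_data_frame(g, what = "edges")
  edges <- data.frame(node_a = el$from, node_b = el$to,
                      stringsAsFactors = FALSE)

  hub_symbol <- NULL
  if (!is.null(planted_hub) && n_nodes >= 2) {
    hub_symbol <- symbols[n_nodes]
    n_wire <- ceiling(planted_hub * (n_nodes - 1))
    targets <- sample(symbols[-n_nodes], n_wire)
    edges <- rbind(edges, data.frame(node_a = hub_symbol, node_b = targets,
                                     stringsAsFactors = FALSE))
  }
  edges$confidence <- stats::runif(nrow(edges), 0.4, 1.0)
  net <- make_network(edges, nodes = symbols, min_confidence = 0.4,
                      source = paste0("synthetic:", topology))
  if (!is.null(hub_symbol)) {
    net <- igraph::set_graph_attr(net, "planted_hub", hub_symbol)
  }
  net
}

#' Generate a synthetic protein identification table
#'
#' Produces `n` protein records of which exactly `round(pass_fraction * n)`
#' satisfy the default evidence thresholds (>= 2 unique peptides and >= 2
#' PSMs); every other record violates at least one threshold. The planted
#' pass count is returned as ground truth.
#'
#' @param n Number of records.
#' @param pass_fraction Fraction of records passing, in [0, 1].
#' @param seed Integer seed.
#' @return List with `records` (a protein record data frame, columns as in
#'   [parse_identifications()]) and `pass_count` (integer ground truth).
#' @export
generate_identifications <- function(n, pass_fraction, seed = 1L) {
  stopifnot(n >= 0, pass_fraction >= 0, pass_fraction <= 1)
  set.seed(as.integer(seed))
  n_pass <- as.integer(round(pass_fraction * n))
  symbols <- synthetic_symbols(n)
  pass <- rep(FALSE, n)
  if (n_pass > 0) pass[sample.int(n, n_pass)] <- TRUE

  unique_peptides <- integer(n)
  psms <- integer(n)
  for (i in seq_len(n)) {
    if (pass[i]) {
      unique_peptides[i] <- sample(2:30, 1)
      psms[i] <- unique_peptides[i] + sample(0:40, 1)
    } else {
      # violate at least one threshold while keeping records internally
      # consistent (a record with >= 1 peptide carries >= 1 PSM)
      mode <- sample(c("few_peptides", "few_psms"), 1)
      if (mode == "few_peptides") {
        unique_peptides[i] <- 1L
        psms[i] <- sample(1:10, 1)
      } else {
        unique_peptides[i] <- sample(2:10, 1)
        psms[i] <- 1L
      }
    }
  }
  records <- data.frame(
    accession = sprintf("SYN%05d", seq_len(n)),
    gene_symbol = symbols,
    unique_peptides = unique_peptides,
    psms = psms,
    is_bait = FALSE,
    stringsAsFactors = FALSE
  )
  list(records = records, pass_count = n_pass)
}

#' Write a protein identification table
#'
#' TSV in the default column dialect, readable by
#' [parse_identifications()].
#'
#' @param records Protein record data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_identifications <- function(records, path) {
  out <- data.frame(
    records$accession, records$gene_symbol,
    records$unique_peptides, records$psms,
    stringsAsFactors = FALSE
  )
  names(out) <- default_id_columns()[c("accession", "gene_symbol",
                                       "unique_peptides", "psms")]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Generate a synthetic annotation table
#'
#' Independent Bernoulli draws per criterion at the stated prevalence.
#'
#' @param symbols Character vector of gene symbols.
#' @param prevalences Named numeric vector, criterion name -> prevalence in
#'   [0, 1].
#' @param seed Integer seed.
#' @return Annotation data frame as from [parse_annotations()].
#' @export
generate_annotations <- function(symbols, prevalences, seed = 1L) {
  stopifnot(all(prevalences >= 0), all(prevalences <= 1),
            !is.null(names(prevalences)))
  set.seed(as.integer(seed))
  out <- data.frame(gene_symbol = symbols, stringsAsFactors = FALSE)
  for (cr in names(prevalences)) {
    out[[cr]] <- stats::runif(length(symbols)) < prevalences[[cr]]
  }
  out
}

#' Published shortlist rank fixture
#'
#' The 20-protein shortlist of the surfactant protein D (rfhSP-D) membrane
#' interactome study, with the printed per-metric dense ranks from the hub,
#' perturbation and disruption analyses and the printed average and
#' cumulative ranks. Used as the exact oracle for the rank-aggregation
#' arithmetic.
#'
#' @return Data frame with columns `protein`, `hub_rank`,
#'   `perturbation_rank`, `disruption_rank`, `average`, `cumulative`.
#' @export
table1_fixture <- function() {
  read.fixture <- function(txt) {
    utils::read.table(text = txt, header = TRUE, stringsAsFactors = FALSE)
  }
  read.fixture("
protein hub_rank perturbation_rank disruption_rank average cumulative
GAPDH     1  1  1  1     1
HSPA8     2  2  3  2.33  2
HSP90AA1  3  3 13  6.33  3
HSPA4     4  6  9  6.33  3
ENO1      6  4 16  8.67  4
TPI1      7 19  2  9.33  5
VCP      11 12  5  9.33  5
CCT2      5 10 15 10     6
HSPA5    12 13  6 10.33  7
LCN2      6 18  8 10.67  8
EEF2     18  8  7 11     9
ACTG1    15  9 10 11.33 10
HSPD1     8 16 12 12    11
PDIA6    16  7 14 12.33 12
CCT8      9 11 17 12.33 12
S100A7   17 20  4 13.67 13
HSPA9    13 17 11 13.67 13
LCN1     19  5 19 14.33 14
HSP90AB1 10 15 20 15    15
CCT5     14 14 18 15.33 16
")
}

#' Published annotation fixture for the 20-protein shortlist
#'
#' The printed annotation flags for the same 20 proteins: expression in
#' prostate glandular cells (human protein atlas), association with
#' prostate cancer (DisGeNET C0376358), with prostate cancer metastasis
#' (DisGeNET C1282496), and with cancer-cell apoptosis (ApocanD / pathway
#' analysis). Provenance labels are attached.
#'
#' @return Annotation data frame with columns `gene_symbol`,
#'   `prostate_expression`, `prostate_cancer`, `prostate_cancer_metastasis`,
#'   `apoptosis`.
#' @export
table2_fixture <- function() {
  txt <- "
gene_symbol prostate_expression prostate_cancer prostate_cancer_metastasis apoptosis
GAPDH    1 1 0 1
HSPA8    1 1 0 1
HSP90AA1 0 1 1 1
HSPA4    1 1 0 1
TPI1     1 0 0 0
ENO1     1 1 0 1
VCP      1 1 0 1
CCT2     1 1 0 1
HSPA5    1 1 1 1
LCN2     0 1 0 1
EEF2     1 1 0 1
ACTG1    1 1 0 0
HSPD1    1 1 0 1
PDIA6    1 0 0 0
CCT8     1 0 0 0
S100A7   0 1 0 1
HSPA9    1 1 0 1
LCN1     0 0 0 0
HSP90AB1 1 1 0 1
CCT5     1 0 0 1
"
  tab <- utils::read.table(text = txt, header = TRUE,
                           stringsAsFactors = FALSE)
  for (col in names(tab)[-1]) tab[[col]] <- tab[[col]] == 1
  attr(tab, "provenance") <- c(
    prostate_expression        = "protein atlas",
    prostate_cancer            = "DisGeNET C0376358",
    prostate_cancer_metastasis = "DisGeNET C1282496",
    apoptosis                  = "ApocanD/IPA"
  )
  tab
}
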
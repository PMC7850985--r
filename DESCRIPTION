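Package: netprio
Title: Network-Based Prioritization of Protein Interactome Candidates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prioritizes proteins from an affinity-purification interactome by
    protein-protein interaction (PPI) network topology. Filters protein
    identifications by spectral evidence (unique peptides and peptide-spectrum
    matches), builds an undirected interaction network from STRING-style edge
    lists, scores every node by hub degree and by two node-deletion measures
    (perturbation of a network centrality index and disruption of shortest
    paths), aggregates the three per-metric dense ranks into a final cumulative
    rank, shortlists the top fraction, and screens the shortlist against
    boolean annotation tables to nominate candidates. Ships a seeded
    synthetic-data generator (scale-free and random topologies, planted hubs,
    evidence tables with controlled pass fractions) so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
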
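#!/usr/bin/env Rscript
# Stage 1: simulate the three pipeline inputs at the study's scale —
# a 672-row protein identification table of which 347 rows pass the
# evidence thresholds, a scale-free PPI network over the same synthetic
# gene symbols, and an annotation table whose per-criterion prevalences
# mirror the published shortlist's annotation rates.

suppressPackageStartupMessages(library(netprio))
suppressPackageStartupMessages(library(jsonlite))

seed <- 2026L
dir <- "results/simulated"
dir.create(dir, recursive = TRUE, showWarnings = FALSE)

ids <- generate_identifications(672, pass_fraction = 347 / 672, seed = seed)
write_identifications(ids$records, file.path(dir, "identifications.tsv"))
cat("identifications: 672 records,", ids$pass_count,
    "planted to pass the evidence thresholds\n")

net <- generate_network(672, "preferential_attachment",
                        attachment_edges = 2, planted_hub = 0.3,
                        seed = seed)
hub <- igraph::graph_attr(net, "planted_hub")
el <- igraph::as_data_frame(net, what = "edges")
writeLines(c("protein1\tprotein2\tcombined_score",
             sprintf("%s\t%s\t%d", el$from, el$to,
                     as.integer(round(el$confidence * 1000)))),
           file.path(dir, "edges.tsv"))
cat("network:", igraph::vcount(net), "nodes,", igraph::ecount(net),
    "edges; planted hub", hub, "at 30% connectivity\n")

# prevalences taken from the published shortlist's annotation rates
prev <- c(prostate_expression = 16 / 20, prostate_cancer = 15 / 20,
          prostate_cancer_metastasis = 2 / 20, apoptosis = 15 / 20)
ann <- generate_annotations(ids$records$gene_symbol, prev, seed = seed)
write_annotations(ann, file.path(dir, "annotations.tsv"))
cat("annotations: 672 symbols x", length(prev), "criteria\n")

jsonlite::write_json(
  list(seed = seed, planted_pass_count = ids$pass_count, planted_hub = hub,
       prevalences = as.list(prev)),
  file.path(dir, "ground_truth.json"), auto_unbox = TRUE, pretty = TRUE)
cat("ground truth written to", file.path(dir, "ground_truth.json"), "\n")
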
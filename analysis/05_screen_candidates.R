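#!/usr/bin/env Rscript
# Stage 5: candidate screen. Intersect the shortlist with the annotation
# criteria (tissue expression, disease, metastasis, apoptosis in the
# simulated tables) and report the proteins satisfying the full
# conjunction, ordered by cumulative rank.

suppressPackageStartupMessages(library(netprio))

short_tab <- utils::read.table("results/shortlist.tsv", header = TRUE,
                               sep = "\t", stringsAsFactors = FALSE)
short <- data.frame(node = short_tab$protein,
                    cumulative_rank = short_tab$cumulative,
                    stringsAsFactors = FALSE)
ann <- parse_annotations("results/simulated/annotations.tsv")
report <- screen_candidates(short, ann)
print(report)
write_candidate_report(report, "results/candidates")
cat("report written under results/candidates_*.tsv\n")
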
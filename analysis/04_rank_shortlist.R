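#!/usr/bin/env Rscript
# Stage 4: rank aggregation. Dense-rank the nodes under the hub (degree),
# perturbation and disruption analyses, average the three ranks, dense-rank
# the averages into the cumulative rank, and shortlist the top 5% without
# splitting tie classes. The bait is excluded from the ranked list.

suppressPackageStartupMessages(library(netprio))

scores <- utils::read.table("results/scores.tsv", header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
ranks <- rank_nodes(scores, bait = "SFTPD", include_bait = FALSE)
write_rank_table(ranks, "results/ranks.tsv")

short <- shortlist_top_fraction(ranks, 0.05)
write_rank_table(short, "results/shortlist.tsv")
cat(sprintf("shortlist: %d of %d proteins (nominal 5%% = %d; ties expand)\n",
            nrow(short), nrow(ranks), ceiling(0.05 * nrow(ranks))))
print(utils::head(short, 10), row.names = FALSE)
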
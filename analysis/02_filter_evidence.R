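#!/usr/bin/env Rscript
# Stage 2: evidence filtering. Keep proteins with >= 2 unique peptides and
# >= 2 PSMs, then add the bait protein (which a pull-down does not identify
# in its own eluate) so it can participate in the network.

suppressPackageStartupMessages(library(netprio))

dir <- "results"
records <- parse_identifications("results/simulated/identifications.tsv")
parts <- filter_identifications(records)
cat(sprintf("evidence filter: %d in / %d kept / %d removed\n",
            nrow(records), nrow(parts$kept), nrow(parts$removed)))

kept <- add_bait(parts$kept, "P35247", "SFTPD")
cat("bait SFTPD (P35247) added:", nrow(kept), "proteins enter the network\n")

write_identifications(kept, file.path(dir, "kept.tsv"))
write_identifications(parts$removed, file.path(dir, "removed.tsv"))
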
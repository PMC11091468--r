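#!/usr/bin/env Rscript
# Normalizes the simulated counts to FPKM and checks the conservation
# identity sum(FPKM * length_kb) = 1e6 per library.

library(regionmarkers)

design <- read_design("results/sim/design.tsv")
counts <- read_counts("results/sim/counts.tsv", design)
lengths <- read_lengths("results/sim/lengths.tsv")

fpkm <- compute_fpkm(counts, lengths)
write_expr_table(fpkm, "results/sim/fpkm.tsv")

totals <- colSums(fpkm * (lengths[rownames(fpkm)] / 1000))
cat("FPKM matrix:", nrow(fpkm), "genes x", ncol(fpkm), "samples\n")
cat("Conservation check, max |sum(FPKM*kb) - 1e6| / 1e6:",
    format(max(abs(totals - 1e6)) / 1e6, digits = 3), "\n")
cat("Wrote results/sim/fpkm.tsv\n")
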
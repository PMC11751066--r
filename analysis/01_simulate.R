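#!/usr/bin/env Rscript
# Step 1 — build the synthetic study inputs.
#
# Emulates the data a promoter-scan screen consumes: one planted repressor
# motif ("FOCAL") plus 24 decoy motifs, 2,000 promoters of 550 bp where 15%
# of genes carry a graded occurrence of the focal motif, and a
# differential-expression table in which the focal targets' expression
# shifts downward with their site strength (effect size 1, noise SD 1).
# Everything is written in the same text formats a real study would supply.

library(tfconcord)

seed <- 42L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

sim <- simulate_dataset(seed = seed)

write_pfm_file(sim$pwms, file.path(out, "motifs.pfm"))
write_promoters_fasta(sim$promoters$sequences,
                      file.path(out, "promoters.fa"))
write.table(sim$de_table, file.path(out, "de_table.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(sim$promoters$truth, file.path(out, "truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("simulated", length(sim$promoters$sequences), "promoters,",
    length(sim$pwms), "motifs (focal:", sim$truth$focal_tf, "as",
    sim$truth$direction, "),",
    sum(sim$promoters$truth$planted), "planted sites\n")
cat("inputs written under", out, "\n")
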
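#!/usr/bin/env Rscript
# Step 3 — the RDE-ranked gene list.
#
# Collapses each gene's (log2FC, FDR) to the signed raw score of
# differential expression, RDE = -sgn(log2FC) * 2^|log2FC| * log10(FDR),
# and ranks the whole transcriptome by it (rank 1 = most upregulated).
# No significance filter: the concordance test needs all genes.

library(tfconcord)

de <- read_de_table("results/data/de_table.tsv")
gene_list <- build_gene_list(de)
write.table(gene_list, "results/gene_list.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(nrow(gene_list), "genes ranked; RDE range",
    round(min(gene_list$rde), 2), "to", round(max(gene_list$rde), 2), "\n")
cat("top of the list:\n")
print(head(gene_list[, c("gene_id", "log2fc", "fdr", "rde", "L_rank")], 3))
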
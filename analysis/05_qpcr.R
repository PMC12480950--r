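#!/usr/bin/env Rscript
# Stage 5: 16S-normalized expression ratios per gene, paired tests with
# BH-FDR across the 7-gene family, and the nosZII vs nosZI comparison.

library(sedshuttle)

ct <- read.csv("results/data/qpcr_ct.csv")
gt <- qpcr_gene_table(ct)
write.csv(gt, "results/qpcr_genes.csv", row.names = FALSE)
print(gt, row.names = FALSE)

rr <- ratio_of_ratios(gt$fold_ratio[gt$gene == "nosZII"],
                      gt$fold_ratio[gt$gene == "nosZI"])
cat(sprintf("nosZII fold-ratio is %.1fx the nosZI fold-ratio\n", rr))
cat(sprintf("%d of %d genes significant at q < 0.05\n",
            sum(gt$q_value < 0.05, na.rm = TRUE), nrow(gt)))
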
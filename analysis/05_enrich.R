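#!/usr/bin/env Rscript
# Fisher's-exact enrichment of the CNV-driven gene list against the cohort's
# gene sets, reported as raw -log10 p with the > 2.0 significance rule.

library(cnvdrive)

co <- generate_cohort(cohort_config())
drv <- read.table("results/driver_genes.tsv", sep = "\t", header = TRUE,
                  stringsAsFactors = FALSE)
enr <- enrich_gene_sets(unique(drv$gene), co$gene_sets, co$genes$gene)
write.table(enr, "results/enrichment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("%d of %d sets significant at -log10 p > 2.0\n",
            sum(enr$significant), nrow(enr)))
print(enr[, c("set", "overlap", "neg_log10_p", "significant")])
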
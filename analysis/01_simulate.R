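#!/usr/bin/env Rscript
# Generate the default synthetic cohort (42 tumor/normal pairs) and write its
# inputs in standard formats under results/cohort/.

library(cnvdrive)

dir.create("results/cohort", recursive = TRUE, showWarnings = FALSE)
cfg <- cohort_config()
co <- generate_cohort(cfg)

write_expression(co$expression, "results/cohort/expression.tsv")
write_bed(co$genes, "results/cohort/genes.bed")
write_gmt(co$gene_sets, "results/cohort/gene_sets.gmt")
write_clinical(co$clinical, "results/cohort/clinical.tsv")

rep <- truth_report(co$truth)
write.table(rep$cnvrs, "results/cohort/truth_cnvrs.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(co$truth$genes, "results/cohort/truth_genes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("cohort: %d pairs, %d genes, %d planted CNVRs\n",
            cfg$n_patients, nrow(co$genes), nrow(cfg$cnvr_specs)))
cat(sprintf("CNVR genes: %d, coupled: %d (%d negatively)\n",
            rep$genes$n_cnvr_genes, rep$genes$n_coupled,
            rep$genes$n_negative))
cat("wrote expression/annotation/gene-set/clinical tables to",
    "results/cohort/\n")
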
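#!/usr/bin/env Rscript
# Stage 2: differential expression for genes and miRNAs.
#
# Two-sided pooled-variance t-tests of case vs control with the strict
# P < 0.01 cutoff; the full signed t-score vector is kept because module
# scoring averages t over members regardless of significance.

library(oncomodule)

dir.create("results/de", showWarnings = FALSE, recursive = TRUE)

genes <- read_expression_tsv("results/synthetic/gene_expression.tsv",
                             "results/synthetic/gene_groups.tsv",
                             case_group = "case")
de_genes <- differential_test(genes, alpha = 0.01)
write.table(de_genes, "results/de/de_genes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

mirnas <- read_expression_tsv("results/synthetic/mirna_expression.tsv",
                              "results/synthetic/mirna_groups.tsv",
                              case_group = "case")
de_mirnas <- differential_test(mirnas, alpha = 0.01)
write.table(de_mirnas, "results/de/de_mirnas.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("\nDEGs at P<0.01:  ", sum(de_genes$is_significant), "/",
    nrow(de_genes), "\n")
cat("DEmiRs at P<0.01:", sum(de_mirnas$is_significant), "/",
    nrow(de_mirnas), "\n")
cat("direction split among DEGs: ",
    sum(de_genes$is_significant & de_genes$direction == "up"), "up / ",
    sum(de_genes$is_significant & de_genes$direction == "down"),
    "down\n")
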
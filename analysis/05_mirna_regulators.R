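#!/usr/bin/env Rscript
# Stage 5: miRNA regulators of the MAOCs.
#
# Every differentially expressed miRNA is tested against every MAOC by a
# one-sided Fisher exact test on its targets (universe: network genes that
# appear in the target map); significant pairs are annotated with the
# direction anti-correlation flag (miRNA change direction opposite to all
# of its in-module targets).

library(oncomodule)

dir.create("results/regulators", showWarnings = FALSE, recursive = TRUE)

net <- read_ppi("results/synthetic/ppi_edges.tsv")
gmt <- read_modules_gmt("results/modules/modules.gmt.tsv")
sel <- read.delim("results/modules/maocs.tsv")
maocs <- gmt$modules[sel$module_id]
de_genes <- read.delim("results/de/de_genes.tsv")
de_mirnas <- read.delim("results/de/de_mirnas.tsv")
target_map <- read.delim("results/synthetic/mirna_targets.tsv")

screen <- regulator_screen(de_mirnas, maocs, target_map,
                           network_genes = igraph::V(net)$name,
                           gene_de = de_genes, alpha = 0.01)

write.table(screen$calls, "results/regulators/regulator_calls.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(screen$edges, "results/regulators/mirna_module_edges.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("\nsignificant (miRNA, MAOC) pairs:", nrow(screen$calls), "\n")
cat("anti-correlated calls:",
    sum(!is.na(screen$calls$anti_correlated) &
          screen$calls$anti_correlated), "\n")
print(screen$calls[, c("mirna", "module_id", "overlap", "enrichment_p",
                       "mirna_direction", "anti_correlated")])

truth <- jsonlite::read_json("results/synthetic/truth.json",
                             simplifyVector = TRUE)
rec <- regulator_recovery(screen$calls, maocs, truth)
cat("planted-regulator recovery:", 100 * rec, "%\n")
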
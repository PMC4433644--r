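#!/usr/bin/env Rscript
# Stage 4: topological key genes of the MAOC network.
#
# Degrees are taken in the subgraph induced by the union of MAOC members;
# hubs are genes with scaled connectivity K = k/k_max strictly above 0.9;
# connector genes are ranked by the number of distinct other MAOCs their
# interaction partners fall in.

library(oncomodule)

dir.create("results/topology", showWarnings = FALSE, recursive = TRUE)

net <- read_ppi("results/synthetic/ppi_edges.tsv")
gmt <- read_modules_gmt("results/modules/modules.gmt.tsv")
sel <- read.delim("results/modules/maocs.tsv")
maocs <- gmt$modules[sel$module_id]
stopifnot(length(maocs) > 0)

deg <- maoc_degrees(net, maocs, scope = "induced")
hubs <- call_hubs(deg$degrees, deg$k_max, threshold = 0.9)
cs <- connecting_scores(net, maocs, min_modules = 2)

write.table(hubs, "results/topology/hubs.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(cs$intra, "results/topology/intra_connectors.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(cs$inter, "results/topology/inter_connectors.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("\nk_max over MAOC genes:", deg$k_max, "\n")
cat("hub genes (K > 0.9):", nrow(hubs), "\n")
print(hubs)
cat("\ntop intra-MAOC connectors:\n")
print(top_connectors(cs$intra, 5))
cat("\ntop inter-MAOC connectors:\n")
print(top_connectors(cs$inter, 5))
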
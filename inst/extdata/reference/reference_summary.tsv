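quantity	value
unique_module_genes	54
deg_fraction_pct	38.89
oral_cancer_overlap_n	30
oral_cancer_overlap_pct	55.56
anti_correlated_mirnas	4
hub_gene_n	4
hub_genes	STAT5B;EGFR;PDGFRB;STAT5A
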
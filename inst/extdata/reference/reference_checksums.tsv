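file	md5
reference_modules.tsv	6ff61d42c8aa8d8ed910766387057007
reference_oral_cancer_genes.tsv	78ab233d2fb5c6c002fa877a0174f266
reference_topology.tsv	ad48994e4d3b7e87b088e42e09c80f1d
reference_regulators.tsv	e2035e793345977c51f843d0bc12086e
reference_summary.tsv	c3e9d6d2e1c628353627e7092f0903a4
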
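role	gene	degree	connecting_score
hub	STAT5B	17	NA
hub	EGFR	16	NA
hub	PDGFRB	16	NA
hub	STAT5A	16	NA
intra	RAF1	10	8
intra	PDGFRB	16	7
intra	SRC	NA	6
intra	PRKACA	NA	6
intra	EGFR	16	4
inter	PRKCA	NA	8
inter	MAPK1	NA	7
inter	MAPK3	NA	7
inter	ESR1	NA	6
inter	FYN	NA	6
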
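module_id	gene	is_deg
M1	DPM3	0
M1	DPM1	0
M1	DPM2	1
M2	HIRA	1
M2	HIST2H2BE	1
M2	HIRIP3	1
M3	EGFR	0
M3	PDGFRB	0
M3	PTPN11	0
M3	SHC1	0
M3	SRC	1
M3	STAT5A	1
M3	STAT5B	1
M3	CBL	0
M4	CSNK2A1	0
M4	NCL	0
M4	TOP1	1
M4	TP53	1
M5	NR3C1	0
M5	POU2F1	1
M5	RARA	0
M5	STAT5A	1
M5	STAT5B	1
M5	NCOR2	0
M6	LRP1	1
M6	SKIL	0
M6	SNX17	0
M7	GNB2	0
M7	GNG4	0
M7	RAF1	1
M8	EGFR	0
M8	INSR	0
M8	LEPR	0
M8	PDGFRA	1
M8	PDGFRB	0
M8	SNX6	0
M8	SNX1	1
M8	SNX2	0
M8	SNX4	0
M8	ACVR1B	0
M8	ACVR2B	0
M9	EGFR	0
M9	JAK2	0
M9	PDGFRB	0
M9	PTPN2	0
M9	PTPN11	0
M9	SRC	1
M9	STAT1	0
M9	STAT3	0
M9	STAT5A	1
M9	STAT5B	1
M10	SIRT1	1
M10	HEY2	0
M10	HES1	1
M11	WNT4	0
M11	SFRP1	0
M11	FZD6	1
M12	PABPC1	0
M12	HNRNPD	1
M12	PCBP1	1
M12	PCBP2	1
M13	PRKACA	0
M13	RAF1	1
M13	RAP1A	1
M13	BRAF	0
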
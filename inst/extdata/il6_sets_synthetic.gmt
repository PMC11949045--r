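inflammation	synthetic stand-in IL6-correlated set	IL6	IL1B	CXCL8	CXCL1	CCL2	TNF	NFKB1	PTGS2
metabolism	synthetic stand-in IL6-correlated set	HK2	PFKP	LDHA	SLC2A1	G6PD	IDH1
cell cycle control/apoptosis	synthetic stand-in IL6-correlated set	CCND1	CDKN1A	BCL2L1	MCL1	BIRC3	XIAP
motility/adhesion	synthetic stand-in IL6-correlated set	ICAM1	ITGA5	ITGB1	MMP9	PLAUR	CD44	THBS1	LAMB3
proliferation	synthetic stand-in IL6-correlated set	MKI67	MYC	CCNB1	PCNA	TOP2A	E2F1
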
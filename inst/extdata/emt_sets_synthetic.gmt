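epithelial	synthetic stand-in EMT phenotype set	CDH1	EPCAM	KRT8	KRT18	CLDN4	CLDN7	OCLN	DSP	ESRP1	GRHL2
hEMT	synthetic stand-in EMT phenotype set	KRT14	KRT5	P4HA2	LAMC2	ITGB4	ITGB6	SNAI1	TNC	VCAN	PDPN
mesenchymal	synthetic stand-in EMT phenotype set	VIM	CDH2	FN1	TWIST1	SNAI2	ZEB1	ZEB2	MMP2	S100A4	FOXC2
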
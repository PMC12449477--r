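ifn_program	interferon-response / chemokine program	IFNG	CXCL9	CXCL10	CXCL13	CXCR6
cytotoxic_lymphocyte	cytotoxic T / NK markers	CD3E	CD8A	GZMB	PTPRC
myeloid_program	monocyte / macrophage markers	CD68	CD163	MSR1	CXCL16
stromal_program	fibroblast / matrix markers	COL1A1	CTNNB1
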
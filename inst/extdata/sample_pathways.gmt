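hsa05210	Colorectal cancer	EGFR	BRAF	RAF1	CTNNB1	GSK3B	AKT1	PIK3CA	MTOR	BCL2	TP53
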
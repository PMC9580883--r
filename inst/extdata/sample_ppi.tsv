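ENTITYA	TYPEA	ENTITYB	TYPEB	EFFECT	MECHANISM	PMID
EGFR	protein	MAPK3	protein	up-regulates activity	phosphorylation	10570924
TP53	protein	BCL2	protein	down-regulates quantity by repression	transcriptional regulation	7834749
AKT1	protein	GSK3B	protein	binds	binding	9072970
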
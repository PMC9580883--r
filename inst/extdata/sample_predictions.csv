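Target,Common name,Uniprot ID,Target Class,Probability*
Epidermal growth factor receptor,EGFR,P00533,Kinase,1
Serine/threonine-protein kinase B-raf,BRAF,P15056,Kinase,0.1042
Glycogen synthase kinase-3 beta,GSK3B,P49841,Kinase,0
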
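ligand_id,protein,energy,probability
quercetin,EGFR,-8.3,1
salicin,GSK3B,-6.1,0.08
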
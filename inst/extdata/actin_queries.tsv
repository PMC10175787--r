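accession	gene	protein_name	length
P62736	ACTA2	Actin, aortic smooth muscle	377
P68032	ACTC1	Actin, alpha cardiac muscle 1	377
P68133	ACTA1	Actin, alpha skeletal muscle	377
P63261	ACTG1	Actin, cytoplasmic 2 (gamma-actin)	375
P63267	ACTG2	Actin, gamma-enteric smooth muscle	376
P60709	ACTB	Actin, cytoplasmic 1 (beta-actin)	375
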
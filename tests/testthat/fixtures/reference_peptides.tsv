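peptide	quantity	value
pep1	length	31
pep1	mol_weight	3415.8067
pep1	pI_bjellqvist	4.5018
pep1	gravy	-0.096774
pep1	instability_index	-7.2258
pep1	ext_reduced	11000
pep1	ext_cystine	11000
pep1	A_mole	3.225806
pep1	C_mole	0.0
pep1	G_mole	16.129032
pep1	W_mole	6.451613
pep2	length	17
pep2	mol_weight	2268.7577
pep2	pI_bjellqvist	9.931
pep2	gravy	-0.517647
pep2	instability_index	13.2235
pep2	ext_reduced	8480
pep2	ext_cystine	8730
pep2	A_mole	0.0
pep2	C_mole	23.529412
pep2	G_mole	5.882353
pep2	W_mole	5.882353
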
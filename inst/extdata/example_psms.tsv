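replicate	condition	spectrum_id	peptide_sequence	protein_ids	psm_probability	peptide_probability	protein_probability
1	PLUS	s001	AAAGLK	P1	0.99	0.99	0.99
1	PLUS	s002	CCWNDK	P1;P2	0.98	0.97	0.99
1	MINUS	s001	AAAGLK	P1	0.8	0.96	0.97
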
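name	paralog	region	first_residue	total_residues	net_charge	sequence
P2Nterm	PTBP2	Nterm	1	57	-1	GALNKQGALNVKRALSVQGESNVQGSSNVSGASSVQGTLNVDGSLNVQGELNDQGAL
P1Nterm	PTBP1	Nterm	1	57	1	GALNVQGALKVQGALSVQGASTVQRALNVQGASNSQGALDVQGAENVQGKLNVQGAL
P2L1	PTBP2	L1	140	39	0	GALNVRGALNVQGATNVQTALTVQSATTVQESLNVQGAL
P1L1	PTBP1	L1	143	42	0	GALRVQGALNVQGSLNSQGALNVQSALNVQGAENVQGALNVQ
P2L2	PTBP2	L2	283	62	-2	GALNVQGDLNVQGKETVQGALNVQGSLNVQGAENVQGALNVQGRLNVEGALNVQGALNVQGA
P1L2	PTBP1	L2	283	84	-2	GALNVQGALNVQGALNVKGALNVQGALDVQGALNVQGELNVQGALNVDGALNVQGALNSQGALNVQGAKNVQGALNVEGALNVQ
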
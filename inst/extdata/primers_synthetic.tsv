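name	marker	forward	reverse	product_min	product_max
rbcL_syn_F1R1	rbcL	ATGTCACCACAAACAGAGAC	GTAAAATCAAGTCCACCRCG	500	620
matK_syn_F1R1	matK	CGTACAGTACTTTTGTGTTTACGAG	ACCCAGTCCATCTGGAAATCTTGGTTC	750	900
rdna_syn_F1R1	rdna	TCCGTAGGTGAACCTGCGG	TCCTCCGCTTATTGATATGC	2300	2600
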
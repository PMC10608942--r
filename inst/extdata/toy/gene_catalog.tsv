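gene_id	contig_id	mag_id	length_bp	ko_id	ec_ids	annot_identity_pct	annot_evalue
a1	cA1	MAG_A	1000	K00001	1.1.1.1	95	1e-30
a2	cA1	MAG_A	500	K00002	NA	50	1e-15
a3	cA2	MAG_A	800	K00001	NA	25	1e-30
a4	cA2	MAG_A	1200	NA	NA	NA	NA
b1	cB1	MAG_B	900	K00002	NA	80	1e-40
b2	cB1	MAG_B	600	K00003	NA	90	1e-05
b3	cB2	MAG_B	1000	K00001	NA	30	1e-10
u1	cU1	UNBINNED	700	K00003	NA	70	1e-20
u2	cU1	UNBINNED	400	NA	NA	NA	NA
u3	cU2	UNBINNED	1100	K00002	NA	45	1e-12
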
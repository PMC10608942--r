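metaprotein_id	peptide_set_id	gene_ids	D1_R1	D1_R2	D2_R1
mp1	PS1	a1	12	16	4
mp2	PS2	a2,b1	9	6	3
mp3	PS3	b1	6	8	20
mp4	PS4	u1	4	6	10
mp5	PS5	b3	2	2	6
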
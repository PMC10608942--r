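gene_id	D1_R1	D1_R2	D2_R1
a1	30	36	10
a2	15	18	5
a3	24	30	8
a4	36	42	12
b1	27	24	45
b2	18	15	30
b3	30	27	50
u1	14	13	21
u2	8	7	12
u3	22	20	33
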
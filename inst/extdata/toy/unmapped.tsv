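sample_id	condition_id	replicate	unmapped_reads
D1_R1	D1	1	25
D1_R2	D1	2	30
D2_R1	D2	1	20
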
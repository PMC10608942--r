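ko_id	gene	product
K02863	rplA	large subunit ribosomal protein L1
K02886	rplB	large subunit ribosomal protein L2
K02906	rplC	large subunit ribosomal protein L3
K02926	rplD	large subunit ribosomal protein L4
K02931	rplE	large subunit ribosomal protein L5
K02933	rplF	large subunit ribosomal protein L6
K02946	rpsJ	small subunit ribosomal protein S10
K02948	rpsK	small subunit ribosomal protein S11
K02950	rpsL	small subunit ribosomal protein S12
K02986	rpsD	small subunit ribosomal protein S4
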
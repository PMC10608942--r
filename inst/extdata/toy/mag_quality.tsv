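mag_id	completeness_pct	contamination_pct	taxonomy	genome_size_bp
MAG_A	80	2	d__Bacteria;p__Firmicutes;c__Clostridia	3500
MAG_B	100	5	d__Bacteria;p__Bacteroidota;c__Bacteroidia	2500
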
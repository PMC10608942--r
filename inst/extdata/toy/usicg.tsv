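ko_id
K00001
K00002
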
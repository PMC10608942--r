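module_id	definition
M0001	K00001,K00002 K00003
M0002	K00001+K00002
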
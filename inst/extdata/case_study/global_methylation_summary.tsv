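tissue	assay	index_percent	ref_mean	ref_sd
PFC	LINE1	67.7	73.0	2.3
PFC	Alu	25.5	28.1	2.6
CER	LINE1	78.4	71.9	2.1
CER	Alu	24.7	24.8	0.8
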
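tissue	skewing_percent
PFC	7.5
CER	0.4
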
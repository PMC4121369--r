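measure	index_value	ref_mean	ref_sd
cerebellum_mass_g	111	170	24
total_brain_mass_g	1417	1410	182
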
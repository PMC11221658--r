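quantity	total
libraries	189
cortical_genes	40348
cortical_lncrnas	20544
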
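category	count
lncRNA	20544
protein_coding	16056
pseudogene	3259
unknown_coding_potential	482
other	7
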
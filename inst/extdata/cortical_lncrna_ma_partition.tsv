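partition	count
ma_grouped	18726
apes	194
uncertain	1624
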
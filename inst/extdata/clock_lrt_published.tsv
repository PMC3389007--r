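locus	statistic	df
COI	55.62	52
ITS2	13.922	21
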
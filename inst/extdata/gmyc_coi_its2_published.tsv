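dataset	n	ll_null_single	ll_gmyc_single	n_species_single	ci_single	ll_null_multiple	ll_gmyc_multiple	n_species_multiple	ci_multiple
COI, complete	58	400.59	561.59	13	13-13	400.59	577.45	17	16-17
COI, pruned	29	148.92	154.76	1	1-1	148.92	151.62	5	4-7
ITS2, complete	22	137.53	170.30	4	4-4	137.53	169.32	7	7-7
ITS2, pruned	14	65.21	66.94	4	1-5	65.21	66.94	4	1-7
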
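pair	K	theta	ratio	n1	n2	p_2clades
P. aotearoa Brazil 1 & Brazil 2	0.04439	0.00667	6.65	5	2	>0.98
P. brasiliensis Europe 1 & Australia 1	0.11017	0.00535	20.67	2	2	>0.99
P. brasiliensis Brazil 3 & Brazil 4	0.0557	0.00118	47.32	10	3	>0.99
P. brasiliensis Brazil 1 & P. reidae	0.13451	0.01073	12.53	2	1	>0.99
P. brasiliensis Brazil 5 & P. kohanga	0.13451	0.02178	6.17	2	1	>0.98
D. stevensoni Europe 2 & Africa 1	0.02155	0.00533	4.04	2	1	0.94
D. stevensoni America 1 & America 2	0.05291	0.00269	19.7	3	1	>0.98
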
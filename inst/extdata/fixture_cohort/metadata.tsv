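group	clade	M	C	alpha	MLS
Porifera	basal	1	0.3	0.75	20
Nematoda	protostome	0.001	0.3	0.72	1
Aves	deuterostome	300	4.5	0.67	18
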
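# Amino-acid lengths of the 13 mtDNA-encoded proteins of the human
# reference mitochondrial genome (NC_012920 / rCRS annotation).
gene	length
ND1	318
ND2	347
ND3	115
ND4	459
ND4L	98
ND5	603
ND6	174
CYTB	380
CO1	513
CO2	227
CO3	261
ATP6	226
ATP8	68
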
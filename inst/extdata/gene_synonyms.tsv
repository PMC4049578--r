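synonym	canonical
ND1	ND1
ND2	ND2
ND3	ND3
ND4	ND4
ND4L	ND4L
ND5	ND5
ND6	ND6
CYTB	CYTB
CO1	CO1
CO2	CO2
CO3	CO3
ATP6	ATP6
ATP8	ATP8
NAD1	ND1
NAD2	ND2
NAD3	ND3
NAD4	ND4
NAD4L	ND4L
NAD5	ND5
NAD6	ND6
NADH1	ND1
NADH2	ND2
NADH3	ND3
NADH4	ND4
NADH4L	ND4L
NADH5	ND5
NADH6	ND6
MT-ND1	ND1
MT-ND2	ND2
MT-ND3	ND3
MT-ND4	ND4
MT-ND4L	ND4L
MT-ND5	ND5
MT-ND6	ND6
MTND1	ND1
MTND2	ND2
MTND3	ND3
MTND4	ND4
MTND4L	ND4L
MTND5	ND5
MTND6	ND6
COX1	CO1
COX2	CO2
COX3	CO3
COI	CO1
COII	CO2
COIII	CO3
COXI	CO1
COXII	CO2
COXIII	CO3
MT-CO1	CO1
MT-CO2	CO2
MT-CO3	CO3
MTCO1	CO1
MTCO2	CO2
MTCO3	CO3
COB	CYTB
CYB	CYTB
COBA	CYTB
MT-CYB	CYTB
MTCYB	CYTB
CYTOCHROMEB	CYTB
ATPASE6	ATP6
ATPASE8	ATP8
ATP-6	ATP6
ATP-8	ATP8
MT-ATP6	ATP6
MT-ATP8	ATP8
MTATP6	ATP6
MTATP8	ATP8
A6	ATP6
A8	ATP8
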
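residue	score
A	0.35
R	-1.50
N	-0.44
D	-0.65
C	0.76
Q	-0.93
E	-0.74
G	0.00
H	-0.65
I	1.10
L	1.18
K	-1.35
M	1.10
F	1.53
P	0.84
S	-0.26
T	-0.18
W	1.53
Y	0.68
V	1.09
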
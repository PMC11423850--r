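element	radius
H	1.20
C	1.70
N	1.55
O	1.52
F	1.47
P	1.80
S	1.80
CL	1.75
BR	1.85
I	1.98
SE	1.90
LI	1.82
NA	2.27
K	2.75
RB	2.90
CS	2.98
MG	1.73
CA	2.31
ZN	1.39
CU	1.40
NI	1.63
FE	1.52
MN	1.61
CO	1.52
CD	1.58
HG	1.55
GA	1.87
IN	1.93
TL	1.96
SN	2.17
PB	2.02
SI	2.10
AS	1.85
TE	2.06
B	1.92
AL	1.84
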
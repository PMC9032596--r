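material	depth_cm	mes_cm
W64A	3	3.82
W64A	15	10.28
W64A	20	12.70
K12	3	2.32
K12	15	3.28
K12	20	5.20
F2:3	3	3.74
F2:3	15	10.95
F2:3	20	13.09
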
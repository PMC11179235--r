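symbol	charge	radius
Li	1	0.76
Na	1	1.02
K	1	1.38
Rb	1	1.52
Cs	1	1.67
Be	2	0.45
Mg	2	0.72
Ca	2	1.00
Sr	2	1.18
Ba	2	1.35
Al	3	0.535
Ga	3	0.62
In	3	0.80
Si	4	0.40
Ge	4	0.53
Sn	4	0.69
Pb	2	1.19
Ti	4	0.605
Ti	3	0.67
Zr	4	0.72
Hf	4	0.71
V	5	0.54
Nb	5	0.64
Ta	5	0.64
Cr	3	0.615
Mn	2	0.83
Fe	2	0.78
Fe	3	0.645
Co	2	0.745
Ni	2	0.69
Cu	1	0.77
Cu	2	0.73
Zn	2	0.74
Ag	1	1.15
Cd	2	0.95
Ce	4	0.87
Y	3	0.90
La	3	1.032
O	-2	1.40
S	-2	1.84
Se	-2	1.98
Te	-2	2.21
F	-1	1.33
Cl	-1	1.81
Br	-1	1.96
I	-1	2.20
N	-3	1.46
H	-1	1.39
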
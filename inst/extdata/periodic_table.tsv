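number	symbol	period	group	mass	covalent_radius
1	H	1	1	1.008	0.31
2	He	1	18	4.0026	0.28
3	Li	2	1	6.94	1.28
4	Be	2	2	9.0122	0.96
5	B	2	13	10.81	0.84
6	C	2	14	12.011	0.76
7	N	2	15	14.007	0.71
8	O	2	16	15.999	0.66
9	F	2	17	18.998	0.57
10	Ne	2	18	20.180	0.58
11	Na	3	1	22.990	1.66
12	Mg	3	2	24.305	1.41
13	Al	3	13	26.982	1.21
14	Si	3	14	28.085	1.11
15	P	3	15	30.974	1.07
16	S	3	16	32.06	1.05
17	Cl	3	17	35.45	1.02
18	Ar	3	18	39.948	1.06
19	K	4	1	39.098	2.03
20	Ca	4	2	40.078	1.76
21	Sc	4	3	44.956	1.70
22	Ti	4	4	47.867	1.60
23	V	4	5	50.942	1.53
24	Cr	4	6	51.996	1.39
25	Mn	4	7	54.938	1.39
26	Fe	4	8	55.845	1.32
27	Co	4	9	58.933	1.26
28	Ni	4	10	58.693	1.24
29	Cu	4	11	63.546	1.32
30	Zn	4	12	65.38	1.22
31	Ga	4	13	69.723	1.22
32	Ge	4	14	72.630	1.20
33	As	4	15	74.922	1.19
34	Se	4	16	78.971	1.20
35	Br	4	17	79.904	1.20
36	Kr	4	18	83.798	1.16
37	Rb	5	1	85.468	2.20
38	Sr	5	2	87.62	1.95
39	Y	5	3	88.906	1.90
40	Zr	5	4	91.224	1.75
41	Nb	5	5	92.906	1.64
42	Mo	5	6	95.95	1.54
43	Tc	5	7	98	1.47
44	Ru	5	8	101.07	1.46
45	Rh	5	9	102.91	1.42
46	Pd	5	10	106.42	1.39
47	Ag	5	11	107.87	1.45
48	Cd	5	12	112.41	1.44
49	In	5	13	114.82	1.42
50	Sn	5	14	118.71	1.39
51	Sb	5	15	121.76	1.39
52	Te	5	16	127.60	1.38
53	I	5	17	126.90	1.39
54	Xe	5	18	131.29	1.40
55	Cs	6	1	132.91	2.44
56	Ba	6	2	137.33	2.15
57	La	6	NA	138.91	2.07
58	Ce	6	NA	140.12	2.04
59	Pr	6	NA	140.91	2.03
60	Nd	6	NA	144.24	2.01
61	Pm	6	NA	145	1.99
62	Sm	6	NA	150.36	1.98
63	Eu	6	NA	151.96	1.98
64	Gd	6	NA	157.25	1.96
65	Tb	6	NA	158.93	1.94
66	Dy	6	NA	162.50	1.92
67	Ho	6	NA	164.93	1.92
68	Er	6	NA	167.26	1.89
69	Tm	6	NA	168.93	1.90
70	Yb	6	NA	173.05	1.87
71	Lu	6	NA	174.97	1.87
72	Hf	6	4	178.49	1.75
73	Ta	6	5	180.95	1.70
74	W	6	6	183.84	1.62
75	Re	6	7	186.21	1.51
76	Os	6	8	190.23	1.44
77	Ir	6	9	192.22	1.41
78	Pt	6	10	195.08	1.36
79	Au	6	11	196.97	1.36
80	Hg	6	12	200.59	1.32
81	Tl	6	13	204.38	1.45
82	Pb	6	14	207.2	1.46
83	Bi	6	15	208.98	1.48
84	Po	6	16	209	1.40
85	At	6	17	210	1.50
86	Rn	6	18	222	1.50
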
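residue	hydropathy_kd	hydrophilicity_hw	sidechain_mass	polarity_grantham	composition_grantham	volume_grantham	isoelectric_point	mol_weight
A	1.8	-0.5	15	8.1	0	31	6	89.1
C	2.5	-1	47	5.5	2.75	55	5.07	121.2
D	-3.5	3	59	13	1.38	54	2.77	133.1
E	-3.5	3	73	12.3	0.92	83	3.22	147.1
F	2.8	-2.5	91	5.2	0	132	5.48	165.2
G	-0.4	0	1	9	0.74	3	5.97	75.1
H	-3.2	-0.5	82	10.4	0.58	96	7.59	155.2
I	4.5	-1.8	57	5.2	0	111	6.02	131.2
K	-3.9	3	73	11.3	0.33	119	9.74	146.2
L	3.8	-1.8	57	4.9	0	111	5.98	131.2
M	1.9	-1.3	75	5.7	0	105	5.74	149.2
N	-3.5	0.2	58	11.6	1.33	56	5.41	132.1
P	-1.6	0	42	8	0.39	32.5	6.3	115.1
Q	-3.5	0.2	72	10.5	0.89	85	5.65	146.2
R	-4.5	3	101	10.5	0.65	124	10.76	174.2
S	-0.8	0.3	31	9.2	1.42	32	5.68	105.1
T	-0.7	-0.4	45	8.6	0.71	61	5.6	119.1
V	4.2	-1.5	43	5.9	0	84	5.96	117.1
W	-0.9	-3.4	130	5.4	0.13	170	5.89	204.2
Y	-1.3	-2.3	107	6.2	0.2	136	5.66	181.2
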
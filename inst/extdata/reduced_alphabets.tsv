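table	residue	group	declared_groups
g2	L	1	2
g2	V	1	2
g2	I	1	2
g2	M	1	2
g2	C	1	2
g2	A	1	2
g2	G	1	2
g2	S	1	2
g2	T	1	2
g2	P	1	2
g2	F	1	2
g2	Y	1	2
g2	W	1	2
g2	E	2	2
g2	D	2	2
g2	N	2	2
g2	Q	2	2
g2	K	2	2
g2	R	2	2
g2	H	2	2
g4	L	1	4
g4	V	1	4
g4	I	1	4
g4	M	1	4
g4	C	1	4
g4	A	2	4
g4	G	2	4
g4	S	2	4
g4	T	2	4
g4	P	2	4
g4	F	3	4
g4	Y	3	4
g4	W	3	4
g4	E	4	4
g4	D	4	4
g4	N	4	4
g4	Q	4	4
g4	K	4	4
g4	R	4	4
g4	H	4	4
g5	L	1	5
g5	V	1	5
g5	I	1	5
g5	M	1	5
g5	C	1	5
g5	A	2	5
g5	G	2	5
g5	S	2	5
g5	T	2	5
g5	P	2	5
g5	F	3	5
g5	Y	3	5
g5	W	3	5
g5	E	4	5
g5	D	4	5
g5	N	4	5
g5	Q	4	5
g5	K	5	5
g5	R	5	5
g5	H	5	5
g8	G	1	8
g8	A	1	8
g8	V	1	8
g8	L	1	8
g8	I	1	8
g8	S	2	8
g8	T	2	8
g8	C	3	8
g8	M	3	8
g8	F	4	8
g8	W	4	8
g8	Y	4	8
g8	H	5	8
g8	K	5	8
g8	R	5	8
g8	D	6	8
g8	E	6	8
g8	N	7	8
g8	Q	7	8
g8	P	8	8
g16	A	1	16
g16	C	2	16
g16	D	3	16
g16	E	4	16
g16	F	5	16
g16	Y	5	16
g16	G	6	16
g16	H	7	16
g16	I	8	16
g16	V	8	16
g16	K	9	16
g16	R	9	16
g16	L	10	16
g16	M	11	16
g16	N	12	16
g16	Q	13	16
g16	P	14	16
g16	S	15	16
g16	T	15	16
g16	W	16	16
g20	A	1	20
g20	C	2	20
g20	D	3	20
g20	E	4	20
g20	F	5	20
g20	G	6	20
g20	H	7	20
g20	I	8	20
g20	K	9	20
g20	L	10	20
g20	M	11	20
g20	N	12	20
g20	P	13	20
g20	Q	14	20
g20	R	15	20
g20	S	16	20
g20	T	17	20
g20	V	18	20
g20	W	19	20
g20	Y	20	20
g25	A	1	25
g25	C	2	25
g25	D	3	25
g25	E	4	25
g25	F	5	25
g25	G	6	25
g25	H	7	25
g25	I	8	25
g25	K	9	25
g25	L	10	25
g25	M	11	25
g25	N	12	25
g25	P	13	25
g25	Q	14	25
g25	R	15	25
g25	S	16	25
g25	T	17	25
g25	V	18	25
g25	W	19	25
g25	Y	20	25
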
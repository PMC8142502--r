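residue	group	group_name
A	1	aliphatic
G	1	aliphatic
I	1	aliphatic
L	1	aliphatic
V	1	aliphatic
S	2	hydroxyl
T	2	hydroxyl
C	3	sulfur
M	3	sulfur
F	4	aromatic
W	4	aromatic
Y	4	aromatic
H	5	basic
K	5	basic
R	5	basic
D	6	acidic
E	6	acidic
N	7	amide
Q	7	amide
P	8	proline
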
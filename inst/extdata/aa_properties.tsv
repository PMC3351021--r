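residue	avg_mass	dayhoff	kyte_doolittle	C	H	N	O	S
A	89.0932	8.6	1.8	3	7	1	2	0
C	121.1582	2.9	2.5	3	7	1	2	1
D	133.1027	5.5	-3.5	4	7	1	4	0
E	147.1293	6.0	-3.5	5	9	1	4	0
F	165.1891	3.6	2.8	9	11	1	2	0
G	75.0666	8.4	-0.4	2	5	1	2	0
H	155.1546	2.0	-3.2	6	9	3	2	0
I	131.1729	4.5	4.5	6	13	1	2	0
K	146.1876	6.6	-3.9	6	14	2	2	0
L	131.1729	7.4	3.8	6	13	1	2	0
M	149.2113	1.7	1.9	5	11	1	2	1
N	132.1179	4.3	-3.5	4	8	2	3	0
P	115.1305	5.2	-1.6	5	9	1	2	0
Q	146.1445	3.9	-3.5	5	10	2	3	0
R	174.2010	4.9	-4.5	6	14	4	2	0
S	105.0926	7.0	-0.8	3	7	1	3	0
T	119.1192	6.1	-0.7	4	9	1	3	0
V	117.1463	6.6	4.2	5	11	1	2	0
W	204.2252	1.3	-0.9	11	12	2	2	0
Y	181.1885	3.4	-1.3	9	11	1	3	0
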
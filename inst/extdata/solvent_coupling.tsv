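# Per-residue solvent couplings eps_i = (Kyte-Doolittle index)/4.5.
# class H (hydrophobic): eps_i > 0, solvent-repulsive;
# classes P (polar) and E (charged): eps_i < 0, solvent-attractive.
residue	class	eps_i	kd_index
A	H	0.400000	1.8
C	H	0.555556	2.5
D	E	-0.777778	-3.5
E	E	-0.777778	-3.5
F	H	0.622222	2.8
G	P	-0.088889	-0.4
H	E	-0.711111	-3.2
I	H	1.000000	4.5
K	E	-0.866667	-3.9
L	H	0.844444	3.8
M	H	0.422222	1.9
N	P	-0.777778	-3.5
P	P	-0.355556	-1.6
Q	P	-0.777778	-3.5
R	E	-1.000000	-4.5
S	P	-0.177778	-0.8
T	P	-0.155556	-0.7
V	H	0.933333	4.2
W	P	-0.200000	-0.9
Y	P	-0.288889	-1.3
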
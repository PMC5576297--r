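# Physicochemical properties of the 20 standard amino acids.
# amino_pka / carboxyl_pka: alpha-amino and alpha-carboxyl group pKa (Lehninger).
# eiip: electron-ion interaction potential, Veljkovic scale (Ry).
# lone_pairs: lone electron pairs on side-chain heteroatoms (N:1, O:2, S:2).
# wiener: Wiener index of the side-chain heavy-atom graph.
# mass: average molecular mass of the free amino acid (Da).
# side_chain_pka: side-chain ionizable group pKa; 0 for non-ionizable side chains.
# hydrophobicity: Kyte-Doolittle hydropathy index.
aa	amino_pka	carboxyl_pka	eiip	lone_pairs	wiener	mass	side_chain_pka	hydrophobicity
A	9.69	2.34	0.0373	0	0	89.09	0	1.8
R	9.04	2.17	0.0959	3	52	174.20	12.48	-4.5
N	8.80	2.02	0.0036	3	9	132.12	0	-3.5
D	9.60	1.88	0.1263	4	9	133.10	3.65	-3.5
C	10.28	1.96	0.0829	2	1	121.16	8.18	2.5
Q	9.13	2.17	0.0761	3	18	146.15	0	-3.5
E	9.67	2.19	0.0058	4	18	147.13	4.25	-3.5
G	9.60	2.34	0.0050	0	0	75.07	0	-0.4
H	9.17	1.82	0.0242	2	26	155.16	6.00	-3.2
I	9.60	2.36	0.0000	0	10	131.17	0	4.5
L	9.60	2.36	0.0000	0	9	131.17	0	3.8
K	8.95	2.18	0.0371	1	20	146.19	10.53	-3.9
M	9.21	2.28	0.0823	2	10	149.21	0	1.9
F	9.13	1.83	0.0946	0	42	165.19	0	2.8
P	10.60	1.99	0.0198	0	4	115.13	0	-1.6
S	9.15	2.21	0.0829	2	1	105.09	0	-0.8
T	9.10	2.11	0.0941	2	4	119.12	0	-0.7
W	9.39	2.38	0.0548	1	106	204.23	0	-0.9
Y	9.11	2.20	0.0516	2	62	181.19	10.07	-1.3
V	9.62	2.32	0.0057	0	4	117.15	0	4.2
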
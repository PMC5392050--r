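index	HW	MW	A	M	B	AMB	AMBnr	Random
S	5	5	18	16	18	4	13	10
Dmg	0.50	0.49	2.07	1.99	2.40	0.35	1.38	1.23
H	1.25	0.91	0.94	1.50	3.13	0.08	0.25	1.19
D	1.79	1.38	1.30	1.68	6.40	1.02	1.05	1.49
J	0.54	0.39	0.22	0.37	0.75	0.04	0.07	0.36
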
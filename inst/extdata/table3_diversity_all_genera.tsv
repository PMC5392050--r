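index	HW	MW	A	M	B	AMB	AMBnr	Random
S	8	6	24	19	23	5	19	10
Dmg	1.03	0.71	3.21	2.27	2.58	2.49	2.57	1.23
H	1.89	1.49	1.72	1.61	1.70	0.09	0.99	1.19
D	2.72	2.10	2.42	2.06	1.78	1.02	1.48	1.49
J	0.63	0.58	0.37	0.37	0.38	0.04	0.23	0.36
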
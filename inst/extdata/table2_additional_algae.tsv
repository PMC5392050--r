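otu	HW	MW	A	M	B	AMB	AMBnr	Random	blast_match
OTU1	0	0	0	0	0	0	10	0	NA
OTU2	89	0	0	0	0	0	0	0	Elliptochloris sp.
OTU3	0	0	4	0	0	0	0	0	NA
OTU4	0	0	5	0	9	0	24	0	Chlorophyta sp. URa28
OTU5	0	0	22	43	147	0	9	0	NA
OTU6	0	0	116	277	372	0	68	0	Chlorophyta sp. URa26
OTU7	29	0	0	0	36	0	0	0	Vulcanochloris guanchorum
OTU8	0	0	8	0	0	0	17	0	Diplosphaera chodati
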
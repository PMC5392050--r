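sample	group	raw_reads	filtered_reads	singletons	unreliable	trebouxia_otus	asterochloris_present	additional_otus
T_jamesii	control	6932	6855	44	33	1	No	0
T_asymmetrica	control	4446	4427	19	0	1	No	0
Mock	control	6970	6935	35	0	2	No	0
TR9	control	6309	6268	41	0	1	No	0
HW	thallusA	4260	4191	69	0	5	Yes	2
MW	thallusA	4741	4683	58	0	5	Yes	0
A	thallusA	6333	6192	105	19	18	Yes	5
M	thallusA	6613	6462	89	57	16	Yes	2
B	thallusA	7017	6848	122	47	18	Yes	4
AMB	thallusA	4947	4910	37	0	5	Yes	0
AMBnr	thallusA	7274	7162	97	15	13	Yes	5
Random	thallusB	1532	1493	39	0	10	No	0
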
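contrast	classification	deseq	edger	bayseq	shared	after_fc_filter	down	up
TEaL_vs_TNL	cervical_dilatation	6	189	128	60	33	3	30
TEsL_vs_TNL	cervical_dilatation	842	403	53	354	251	58	193
TEsL_vs_TEaL	cervical_dilatation	0	1	11	1	0	0	0
TL-ROM_vs_TNL	fetal_membrane_rupture	13	96	81	37	20	6	14
TL+ROM_vs_TNL	fetal_membrane_rupture	838	701	151	578	426	43	383
TL+ROM_vs_TL-ROM	fetal_membrane_rupture	2	5	5	0	0	0	0
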
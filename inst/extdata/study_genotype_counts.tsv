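variant_id	gene	model	genotype	n_case	n_control
rs45472704	TREH	IBS	A/A	1	0
rs45472704	TREH	IBS	A/G	41	12
rs45472704	TREH	IBS	G/G	645	427
rs2277296	TREH	IBS	C/C	27	24
rs2277296	TREH	IBS	C/T	211	164
rs2277296	TREH	IBS	T/T	449	251
rs2277297	TREH	IBS	T/T	27	24
rs2277297	TREH	IBS	T/C	211	164
rs2277297	TREH	IBS	C/C	449	251
rs17748	TREH	IBS-C	T/T	2	24
rs17748	TREH	IBS-C	T/C	33	155
rs17748	TREH	IBS-C	C/C	89	260
rs75172324	SI	IBS-C	C/C	14	73
rs75172324	SI	IBS-C	C/CA	50	210
rs75172324	SI	IBS-C	CA/CA	60	144
rs75172324	SI	IBS-C	C(del)	0	12
rs130406	SLC5A1	IBS-C	A/A	20	114
rs130406	SLC5A1	IBS-C	A/G	60	199
rs130406	SLC5A1	IBS-C	G/G	44	126
rs113665082	SLC2A5	IBS-U	T/T	0	0
rs113665082	SLC2A5	IBS-U	T/C	7	6
rs113665082	SLC2A5	IBS-U	C/C	101	433
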
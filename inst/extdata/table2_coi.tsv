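haplotype	lineage	52	136	142	160	166	172	178	181	211	241	268	304	305	307	310	331	334	358	364	365	374	394	430	451	454	457	463	466	502	511	523	freq	Bpl	Cad	Ber	Azo	Mad	Can	Bra	Arg	Saf	SafB	Ind	Aus	Nze
PamCOI.1	americanus	C	C	G	T	A	C	T	C	A	C	G	T	T	A	A	A	A	T	T	T	G	C	G	G	C	C	C	G	T	A	T	26	6	1	2	5	3	9	0	0	0	0	0	0	0
PamCOI.2	americanus	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	C	.	.	.	.	.	.	.	.	.	.	.	G	.	4	0	0	0	0	0	0	3	1	0	0	0	0	0
PamCOI.3	americanus	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	G	.	6	0	0	0	0	0	0	4	2	0	0	0	0	0
PamCOI.4	americanus	.	.	.	C	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	.	A	.	.	.	.	.	.	.	.	G	.	4	0	0	0	0	0	0	0	0	0	0	1	2	1
PamCOI.Saf	saf	T	T	A	.	G	T	.	A	.	A	A	C	.	G	.	G	.	.	C	C	A	.	.	.	T	T	T	A	C	.	.	6	0	0	0	0	0	0	0	0	4	2	0	0	0
PoxyCOI.1	oxygeneios	.	.	.	.	.	.	C	A	G	.	A	.	C	.	G	G	C	.	C	.	.	.	A	A	.	T	T	.	.	.	C	4	0	0	0	0	0	0	0	0	0	0	1	3	0
PoxyCOI.2	oxygeneios	.	.	.	.	.	.	C	A	G	.	A	.	C	.	G	G	C	.	C	.	.	T	C	A	.	T	T	.	.	.	C	1	0	0	0	0	0	0	0	0	0	0	0	1	0
PoxyCOI.3	oxygeneios	.	.	.	.	.	.	C	A	G	.	A	.	C	.	G	G	C	.	C	.	.	T	C	A	.	.	T	.	.	.	C	1	0	0	0	0	0	0	0	0	0	0	0	1	0
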
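upn	sample_id	years_prior	gene	chr	position	mut	aa_change	variant_rfs	reference_rfs	vaf_printed
446294	75.02	1	OBSCN	1	228461129	A to G	H1857R	61238	156986	0.2806
446294	75.02	1	TP53	17	7578271	T to A	H193L	220551	110047	0.6671
499258	24.06	2	RUNX1	21	36252865	C to G	R139P	2	486196	0
574214	26.04	7	DMD	X	32827676	G to A	R187*	7	199945	0
643006	80.01	12	ASXL1	20	31022448	G to T	G645C	7	85781	0.0001
643006	80.01	12	ASXL1	20	31022442	del G	G645fs	2898	82245	0.034
643006	80.01	12	GATA2	3	128200135	del CTT	K390in_fr_del	0	4187	0
643006	80.01	12	U2AF1	21	44524456	G to T	S34Y	85	414613	0.0002
684949	91.01	5	ASXL1	20	31023112	T to G	L866*	3583	853598	0.0042
684949	91.01	5	U2AF1	21	44524456	G to T	S34Y	545	514410	0.0011
684949	92.02	4	ASXL1	20	31023112	T to G	L866*	54074	535976	0.0916
684949	92.02	4	U2AF1	21	44524456	G to T	S34Y	11195	355276	0.0305
684949	93.01	3	ASXL1	20	31023112	T to G	L866*	17319	573629	0.0293
684949	93.01	3	U2AF1	21	44524456	G to T	S34Y	827	92104	0.0089
856024	30.02	1	S100A4	1	153517192	A to G	F27L	0	211512	0
856024	30.02	1	IGSF8	1	160062252	G to A	P516S	0	22614	0
856024	30.02	1	PLA2R1	2	160798389	A to G	L1431P	2	338616	0
856024	30.02	1	POU3F2	6	99282794	C to A	S15R	8	201240	0
856024	30.02	1	ANKRD18B	9	33524645	G to A	C53Y	7	214836	0
856024	30.02	1	ESR2	14	64701847	G to A	A416V	10	135861	0.0001
856024	30.02	1	FBN3	19	8155081	G to A	P2029L	0	152304	0
942008	33.04	9	IDH2	15	90631934	C to T	R88Q	23170	236587	0.0892
942008	33.04	9	RUNX1	21	36231791	T to C	D171G	40	253168	0.0002
942008	107.01	<1	IDH2	15	90631934	C to T	R88Q	138180	161371	0.4613
942008	107.01	<1	RUNX1	21	36231791	T to C	D171G	368438	50796	0.8788
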
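probe_id	chromosome	gene	cvs_mean	mbc_mean	delta	refseq	msre
cg00674220	13	USP12	0.09	0.86	0.77	NM_182488	AciI
cg00812799	13	IL17D	0.19	0.79	0.59	NM_138284	HhaI
cg01131395	13	LRCH1	0.21	0.88	0.66	NM_001164211	HpyCH4IV
cg02294416	13	DIAPH3-AS1	0.21	0.79	0.58	NR_046539	HpyCH4IV
cg03202693	13	MCF2L	0.11	0.92	0.82	NM_001112732	HpaII
cg03502979	13	ADPRHL1	0.11	0.80	0.68	NM_138430	HpaII
cg05769384	13	GTF2F2	0.19	0.82	0.63	NM_004128	HpyCH4IV
cg06568438	13	NDFIP2-AS1	0.15	0.89	0.73	NR_046685	AatII
cg09069900	13	F10	0.11	0.91	0.80	NM_000504	AciI
cg09238199	13	COL4A2-AS1	0.86	0.06	0.79	NR_046583	HpyCH4IV
cg10765171	13	BASP1P1	0.16	0.83	0.67	NR_033774	BstUI.1
cg11440915	13	LMO7	0.20	0.90	0.70	NM_005358	AciI
cg12601059	13	OR7E37P	0.18	0.83	0.65	NR_002163	HpaII
cg13054419	13	MEDAG	0.16	0.87	0.72	NM_032849	HpaII
cg16184802	13	PCDH9-AS3	0.16	0.81	0.65	NR_046636	HpyCH4IV
cg17313432	13	MYO16-AS1	0.12	0.89	0.76	NR_047700	HpaII
cg18158859	13	EFNB2	0.93	0.16	0.76	NM_004093	HpaII
cg18582260	13	PARP4	0.90	0.18	0.72	NM_006437	HhaI
cg19300307	13	STK24	0.08	0.87	0.79	NM_001032296	HpyCH4IV
cg20798249	13	MLNR	0.17	0.90	0.74	NM_001507	AciI
cg21478902	13	COL4A1	0.17	0.87	0.70	NM_001845	BstUI.1
cg21851395	13	MIR5006	0.14	0.87	0.73	NR_049803	HpyCH4IV
cg22478679	13	ADPRHL1	0.18	0.83	0.65	NM_138430	HpaII
cg26082814	13	ADPRHL1	0.13	0.84	0.70	NM_138430	AciI
cg26273417	13	EFNB2	0.81	0.10	0.72	NM_004093	AciI
cg27395757	13	C13orf35	0.21	0.87	0.66	NM_207440	AciI
cg03987884	18	HMSD	0.21	0.82	0.61	NM_001123366	BstUI.1
cg12931591	18	TGIF1	0.13	0.88	0.75	NM_003244	AciI
cg13572782	18	MBP	0.17	0.82	0.65	NM_001025081	HpaII
cg16177732	18	VAPA	0.84	0.08	0.75	NM_003574	AciI
cg17266581	18	MBP	0.08	0.95	0.86	NM_001025081	HpaII
cg25951288	18	NFATC1	0.10	0.97	0.87	NM_006162	HpaII
cg01579765	21	HSF2BP	0.87	0.15	0.72	NM_007031	ClaI
cg06925304	21	COL6A2	0.23	0.87	0.65	NM_001849	HpaII
cg08443845	21	RUNX1	0.82	0.07	0.74	NM_001001890	AciI
cg08449975	21	DSCR8	0.12	0.90	0.77	NM_032589	BstUI.2
cg09714100	21	SIK1	0.19	0.89	0.69	NM_173354	HpaII
cg10375884	21	IFNAR2	0.19	0.84	0.66	NM_000874	HpaII
cg11113661	21	ICOSLG	0.19	0.97	0.78	NM_015259	EagI.1
cg15220969	21	SIK1	0.79	0.18	0.62	NM_173354	HpaII
cg16412370	21	HSF2BP	0.21	0.83	0.62	NM_007031	BstUI.1
cg16424439	21	ICOSLG	0.17	0.89	0.72	NM_015259	HpaII
cg22434923	21	PTTG1IP	0.08	0.81	0.73	NM_004339	AgeI
cg24343720	21	CLDN17	0.19	0.78	0.59	NM_012131	HpyCH4IV
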
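orf	start	end	nt	aa	best_hit	species	evalue	pct_aa_identity	aln_len_aa
1	1	786	786	261	Hypothetical protein YSLV3_ORF01	YSLV3	8e-134	70	254
2	1649	783	867	288	Hypothetical protein BpV2_168	Bathycoccus sp. RCC1105 virus BpV2	2e-14	27	186
3	1876	2121	246	81	Hypothetical protein YSLV3_ORF12	YSLV3	2e-12	39	74
4	2328	4901	2574	857	Putative primase-helicase	YSLV3	3e-169	37	781
5	4957	5388	432	143	Hypothetical protein YSLV3_ORF10	YSLV3	1e-19	36	129
6	5440	6375	936	311	Hypothetical protein YSLV3_ORF09	YSLV3	2e-123	58	307
7	6398	8362	1965	654	Hypothetical protein YSLV3_ORF06	YSLV3	4e-85	75	171
8	9164	8493	672	233	Hypothetical protein YSLV3_ORF13	YSLV3	1e-69	50	210
9	9222	10679	1458	495	Hypothetical protein YSLV3_ORF14	YSLV3	7e-33	50	152
10	10730	11299	570	189	NA	NA	NA	NA	NA
11	11340	12761	1422	473	NA	NA	NA	NA	NA
12	12807	14093	1287	428	Hypothetical protein YSLV3_ORF16	YSLV3	2e-25	37	204
13	14150	14464	315	104	Hypothetical protein YSLV3_ORF17	YSLV3	3e-26	59	93
14	14858	16090	1233	410	Putative minor capsid protein	YSLV3	1e-142	55	408
15	16147	17874	1728	575	Putative major capsid protein	YSLV3	0	68	538
16	18575	18138	438	145	Cysteine desulfurase	Citreicella sp. SE45	1.4	26	104
17	19079	19321	243	80	NA	NA	NA	NA	NA
18	19886	19296	591	196	NA	NA	NA	NA	NA
19	20100	20450	351	116	NA	NA	NA	NA	NA
20	21490	20447	1044	347	Serine protease	Streptococcus sanguinis	0.010	29	131
21	23639	21303	2337	778	Hypothetical protein YSLV3_ORF22	YSLV3	3e-40	37	246
22	23704	23931	228	75	NA	NA	NA	NA	NA
23	26100	24067	2034	677	Hypothetical protein YSLV3_ORF21	YSLV3	7e-57	33	650
24	26396	26205	192	63	NA	NA	NA	NA	NA
25	27017	26496	522	173	Hypothetical protein NY2A_B677R	Paramecium bursaria Chlorella virus NY2A	2e-31	45	116
26	27061	27339	279	92	NA	NA	NA	NA	NA
27	27249	27860	612	203	Hypothetical protein PGVV_00006	Phaeocystis globosa virus virophage	8e-05	33	85
28	27918	28748	831	276	Hypothetical protein YSLV3_ORF23	YSLV3	3e-123	63	275
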
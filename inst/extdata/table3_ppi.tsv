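ranking	gene_id	gene_symbol	total_interactions	query_interactions
22	10038	PARP2	6	3
36	10717	AP4B1	4	2
37	8881	CDC16	12	3
43	996	CDC27	26	4
47	51434	ANAPC7	9	2
48	26271	FBXO5	6	2
49	8546	AP3B1	12	2
50	5528	PPP2R5D	11	2
51	23468	CBX5	35	4
53	5494	PPM1A	16	2
54	9400	RECQL5	16	2
56	5525	PPP2R5A	21	2
57	10982	MAPRE2	8	2
58	675	BRCA2	28	2
59	891	CCNB1	35	2
60	51421	AMOTL2	11	2
61	57562	KIAA1377	81	4
62	163	AP2B1	33	2
63	22981	NINL	37	2
64	11335	CBX3	18	2
65	7277	TUBA4A	61	3
66	10459	MAD2L2	13	2
67	5684	PSMA3	37	2
68	890	CCNA2	36	2
69	324	APC	43	3
70	162	AP1B1	21	2
71	22919	MAPRE1	16	2
72	1874	E2F4	78	3
73	26258	PLDN	21	2
74	3066	HDAC2	85	3
75	142	PARP1	56	3
76	983	CDC2	131	4
77	5515	PPP2CA	59	2
78	7343	UBTF	27	2
79	81565	NDEL1	26	2
80	55290	BRF2	57	2
81	3065	HDAC1	162	5
82	5499	PPP1CA	82	3
83	1639	DCTN1	47	2
84	203068	TUBB	95	2
85	23043	TNIK	90	2
86	28964	GIT1	53	2
87	1869	E2F1	89	3
88	3692	EIF6	101	2
89	5921	RASA1	69	2
90	55183	RIF1	106	2
91	5764	PTN	86	2
92	8848	TSC22D1	103	2
93	11156	PTP4A3	101	2
94	7046	TGFBR1	160	2
95	5925	RB1	156	2
96	7428	VHL	208	2
97	7157	TP53	315	2
98	7189	TRAF6	369	2
99	7532	YWHAG	309	2
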
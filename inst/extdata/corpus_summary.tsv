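substance	n_reports	mean_sentences	sd_sentences	min_sentences	median_sentences	max_sentences
Cannabis	3039	54.4	51.9	1	41	995
MDMA	2507	56.7	58.6	1	42	979
LSD	2488	80	82.8	1	59	1396
Salvia divinorum	2450	54.4	44	1	44	498
Mushrooms	2283	68.3	59.3	1	55	916
DMT	1121	62.9	54.9	2	47	583
DXM	869	50.2	51.9	2	35	582
Mushrooms_P. cubensis	812	81.2	70.3	1	65.5	916
Cocaine	810	40.7	36	1	30.5	284
Ketamine	796	57.1	54	1	42	511
Morning Glory	647	59.4	50.7	2	47	520
Amphetamines	642	48.7	45.7	1	37	428
Kratom	594	39.6	44.4	1	30	428
2C-I	576	63.5	48.1	3	50	310
Methamphetamine	574	53.5	63.8	4	37	965
Syrian Rue	545	69.9	56.1	6	54	439
H.B. Woodrose	521	55.6	44.9	1	47	336
Nitrous Oxide	495	49.6	49.5	1	35	459
2C-B	469	61.1	47.2	4	50	389
2C-E	449	71.9	64.6	1	56	506
Heroin	430	50.1	43.8	2	39	399
Oxycodone	427	43.3	36.8	2	33	323
5-MeO-DMT	409	54.5	46.7	4	43	453
Alcohol	407	39	30	3	31	248
Pharms_Tramadol	403	31.3	32.3	2	22	388
Nutmeg	387	42.8	40	1	32	329
Pharms_Zolpidem	377	32.4	30.6	1	23	308
Diphenhydramine	375	48.6	37.5	1	39	228
Datura	353	53.6	42.9	1	40	303
Amanitas_A. muscaria	336	49.2	49.8	1	36.5	478
Hydrocodone	333	36.7	27.4	1	28	186
Pharms_Alprazolam	325	37.4	40.4	1	23	286
Caffeine	321	32	25.3	2	25	168
5-MeO-DiPT	320	49.8	38.2	3	37	249
4-AcO-DMT	316	76	53.7	7	62	361
AMT	313	59	50.1	4	44	410
Cacti_T. pachanoi	302	68.9	62.3	4	52	507
Alcohol_Beer_Wine	288	36.6	30.9	2	27	228
Alcohol_Hard	282	41.1	29.9	3	33	225
Pharms_Clonazepam	280	31.2	29.2	2	22	224
Kava	272	27.6	17.9	3	22	108
Pharms_Buprenorphine	256	33	33.7	1	24	277
Codeine	252	34.4	26.6	2	26	141
2C-T-7	246	54.2	42.3	1	43	329
25I-NBOMe	244	69.1	43.9	7	59	328
Dimenhydrinate	243	51.4	35.5	3	44	263
Methoxetamine	243	63.9	70.7	3	43	527
Pharms_Methylphenidate	240	47	57	2	31	428
Mimosa tenuiflora	236	81.6	65.7	7	63.5	583
DPT	235	62.8	44.6	2	50	224
Inhalants	220	36.6	60.3	3	27	853
GHB	217	40.4	39.8	5	28	325
Modafinil	210	34.2	32.4	3	25.5	266
Huasca Combo	203	76.7	52.6	9	61	338
Products_Spice-Like Smoking Blends	197	52.3	44.8	4	39	316
Methylone	194	58.4	49.2	3	46.5	305
Ayahuasca	193	103.5	86.4	7	81	568
Pharms_Bupropion	190	36.3	36	2	25	240
Pharms_Gabapentin	186	30.3	26	2	23	184
2C-T-2	177	54.2	47.2	6	39	280
Pharms_Venlafaxine	176	29.3	27.9	4	22	214
Methadone	164	35.2	37	4	23	259
Morphine	157	36.7	36.1	3	27	305
4-Methylmethcathinone	156	52.5	84.5	4	35	995
Tobacco	154	35.4	37.9	3	22.5	241
MDA	148	52.4	30.9	6	44	158
Calea zacatechichi	147	31.3	24.6	3	25	178
Poppies_Opium	146	41.7	37.2	7	32	299
Banisteriopsis caapi	145	82.1	63.6	4	65	443
Melatonin	143	22.7	19	1	16	134
Pharms_Paroxetine	142	31.1	27.1	2	22	195
Crack	140	37.4	33	1	27	238
Pharms_Quetiapine	137	28.3	27	3	19	148
Cannabis_Hash	137	50.3	43.6	7	37	248
Lotus_Lily_Nymphaea nouchali var. caerulea	137	33.8	24.7	2	26	133
5-MeO-AMT	137	52.2	40.2	2	43	269
Pharms_Pregabalin	136	28.2	21.3	3	21.5	107
Absinthe	133	30	21	3	25	119
25C-NBOMe	128	66.8	50.1	7	52	281
Smarts_Phenibut	125	43.1	38.1	4	34	263
Damiana	124	23.1	20.2	4	18	119
Pharms_Diazepam	124	41.7	38.7	3	30.5	224
1P-LSD	122	74.7	58.2	2	62.5	348
PCP	122	44.8	30.7	6	36	157
Catnip	121	22.2	17.1	3	17	133
Valerian	118	25.8	25.6	2	19	177
4-HO-MET	116	73.1	48.1	1	61	275
Cacti_T. peruvianus	115	87.5	114.2	4	63	977
Pharms_Fentanyl	114	33.4	26.3	2	26	141
2C-C	114	59.1	51.7	6	39.5	294
5-MeO-MIPT	114	61.8	45.2	8	47	225
MDPV	113	39.8	36.6	5	26	185
Etizolam	113	41.7	48	3	29	307
Pharms_Lorazepam	109	38.1	36	2	26	184
JWH-018	106	50.4	41.6	5	40	246
Sceletium tortuosum	104	30.5	30	6	23	201
Wormwood	104	27.7	19.4	3	25.5	119
DOC	104	87.5	64.8	7	69	373
Pharms_Sertraline	104	32.6	27.5	5	24	156
Mescaline	104	86.8	92.7	8	65	654
Brugmansia	103	58.1	40.7	2	44	162
Piracetam	103	37.6	41.9	4	26	369
Huasca Brew	102	85.3	64.6	13	66	362
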
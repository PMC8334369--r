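feature_id	S01_T1	S02_T1	S03_T1	S04_T1	S05_T1	S06_T2	S07_T2	S08_T2	S09_T2	S10_T2	S11_T2	S12_T2	S13_NORM	S14_NORM	S15_NORM	S16_NORM	S17_NORM	S18_NORM	S19_NORM	S20_NORM	S21_PE	S22_PE	S23_PE	S24_PE	S25_PE	S26_PE	S27_PE	S28_PE	S29_GD	S30_GD	S31_GD	S32_GD	S33_GD	S34_GD	S35_GD	S36_GD	S37_SGA	S38_SGA	S39_SGA	S40_SGA	S41_SGA	S42_SGA	S43_SGA	S44_SGA	S45_LGA	S46_LGA	S47_LGA	S48_LGA	S49_LGA	S50_LGA	S51_LGA	S52_LGA
mir001	202	154	106	322	177	73	86	81	82	33	32	52	211	182	220	170	198	295	141	123	174	237	160	117	230	157	156	225	201	124	256	219	184	233	221	139	222	156	194	212	317	206	335	166	200	203	177	294	253	233	163	196
mir002	184	124	164	203	197	151	96	216	96	204	105	122	174	143	273	112	139	109	133	121	99	142	115	135	168	144	176	146	106	160	103	103	128	177	131	115	191	92	172	154	135	106	83	97	121	103	160	105	141	142	212	127
mir003	139	107	104	159	105	116	94	113	129	142	93	113	115	61	116	106	88	89	94	132	88	117	120	136	73	78	94	82	111	87	186	67	88	193	88	135	165	81	144	108	143	119	118	114	136	120	74	138	116	126	133	119
mir004	47	33	32	34	27	47	27	58	42	33	33	59	308	168	275	209	262	243	293	199	396	512	752	564	515	600	399	539	242	270	363	290	234	278	305	234	221	351	186	308	346	131	295	141	206	157	200	401	256	292	160	134
mir005	18	24	52	22	47	36	18	35	44	48	25	23	28	38	39	46	42	53	33	29	10	16	9	6	25	23	8	13	30	31	40	36	41	39	21	36	25	50	40	60	53	21	40	21	53	17	34	53	34	29	25	53
mir006	668	448	347	253	581	745	517	1247	253	943	298	288	127	15	21	64	34	44	46	17	41	65	74	24	22	109	31	51	25	66	68	30	66	158	53	18	75	114	35	26	45	76	83	26	73	33	20	33	80	39	22	30
mir007	217	243	329	466	133	165	74	42	98	117	38	39	283	208	1240	301	615	278	356	566	979	1812	1028	337	561	539	371	308	226	676	255	610	566	683	364	167	232	350	245	324	632	414	947	448	475	562	270	765	210	572	463	233
mir008	199	229	221	205	220	6	3	7	6	4	6	8	17	10	23	15	8	18	11	22	4	17	11	7	15	24	18	11	9	26	21	17	14	9	19	18	31	14	10	13	14	18	12	10	11	13	20	29	20	14	9	20
mir009	1576	3314	3319	2265	2230	2739	1049	2108	1344	2749	1864	1209	2298	1576	2435	1097	1677	1804	1698	2031	1882	1781	1324	2036	1959	3999	1517	1568	2007	2406	2148	2366	2522	2717	2294	1678	1825	1925	2639	2670	2449	2561	1976	1076	1609	2254	1397	2379	2436	2731	1366	1423
mir010	231	244	276	326	146	250	155	270	188	208	305	254	200	231	325	200	303	353	237	186	275	353	120	123	266	250	248	296	155	211	397	260	157	235	173	135	248	347	248	198	216	215	211	248	221	422	178	226	213	346	248	109
mir011	120	110	86	161	198	115	104	130	88	181	97	185	556	473	695	561	603	716	610	565	530	1107	570	523	473	661	634	318	519	520	767	771	678	679	716	919	705	532	872	797	971	546	693	394	827	619	689	727	507	803	549	696
mir012	225	150	181	174	230	211	137	223	185	214	152	226	220	195	231	177	197	220	189	152	194	259	131	138	203	178	159	150	118	139	164	139	239	298	190	129	123	208	187	250	149	209	213	221	171	194	212	191	213	217	131	158
mir013	1432	1782	3368	2887	5966	1630	4511	3565	1709	2251	991	2906	9467	6785	12664	6309	9392	6106	3954	7976	6869	8086	5176	15510	18285	16173	8856	10600	25319	7110	15872	9549	19669	8249	7884	7092	12382	42207	7190	11160	8268	17757	5057	7035	4894	7845	6473	7088	6370	7895	6320	7090
mir014	110	95	89	120	53	81	69	132	73	151	95	84	81	67	92	105	67	100	42	60	93	121	71	65	51	100	75	42	43	117	135	93	107	103	56	68	87	78	104	101	82	39	32	70	55	78	119	74	73	121	82	44
mir015	374	134	376	142	255	454	423	699	795	544	449	351	57	144	104	189	86	172	158	72	64	108	147	59	78	155	74	76	78	382	180	84	102	121	50	78	82	94	144	47	159	46	41	103	194	149	72	177	79	105	57	62
mir016	536	423	690	617	518	623	370	393	262	323	544	572	1951	1235	1870	1574	1799	1152	944	892	1126	1418	1387	1983	1479	1627	1260	1348	1094	1390	2781	1610	1525	1751	1204	1096	1978	1325	1111	1667	1957	1391	1524	1249	1315	2011	1499	1552	1631	2758	1405	1164
mir017	458	514	562	700	498	1915	1143	1256	864	1791	1423	1358	1968	1440	2347	1406	1354	1995	1862	1216	1655	2605	1964	1257	1507	1399	2203	1268	1045	2068	1773	1355	1667	1673	1741	1661	1642	1777	1442	1071	1904	1500	1587	989	1805	1026	1421	2355	957	2005	1328	1617
mir018	622	501	446	672	686	765	409	923	721	543	1051	637	578	316	772	393	760	779	787	492	617	799	689	563	618	768	725	360	464	672	1330	747	686	671	613	662	367	678	599	773	573	345	904	460	492	545	467	630	835	758	519	448
mir019	87	113	86	112	119	47	31	44	26	44	48	31	28	28	49	63	42	47	28	30	82	82	53	65	138	132	106	64	33	42	62	30	47	54	52	29	40	63	25	41	42	44	42	43	51	35	48	64	22	59	18	41
mir020	87	55	77	74	48	19	19	23	8	18	34	25	172	118	211	138	122	100	175	78	103	175	138	172	159	159	135	84	81	151	105	142	153	175	93	228	143	212	151	236	175	133	98	140	193	132	141	133	175	121	87	103
mir021	297	180	403	191	275	21	10	18	15	25	23	11	3	1	5	3	5	3	3	3	1	7	2	2	4	3	3	3	0	5	5	2	2	6	1	4	5	5	4	0	1	1	4	8	2	3	4	2	2	2	1	2
mir022	142	110	76	137	62	129	100	132	112	116	108	160	73	115	185	139	146	58	88	86	196	238	189	195	222	358	159	307	110	107	149	153	135	112	96	112	155	115	114	147	129	109	181	59	135	120	96	175	127	209	145	113
mir023	93	129	86	84	96	198	196	428	115	384	217	213	1508	756	1653	888	1153	1545	1312	840	1192	1975	1440	911	993	1731	1513	1114	1259	1322	1456	1658	1528	2057	1128	1479	1867	1290	1272	1043	1214	1212	849	902	1355	1698	1538	1327	1254	1472	1021	938
mir024	534	881	721	406	1093	377	385	2735	1210	494	618	378	2038	1002	1467	2398	1352	1487	873	1676	1535	2829	1427	1829	1099	2633	1180	965	1053	1518	3350	2229	1270	2171	1629	1025	2352	934	5734	2159	2802	1159	3171	839	3060	3156	1040	4772	6267	1806	1299	715
mir025	44	47	51	68	35	0	1	0	2	3	0	4	0	3	1	7	2	0	1	4	0	5	2	2	2	1	1	2	1	2	0	3	1	2	3	1	2	2	2	2	3	3	0	0	3	1	3	4	1	3	0	1
mir026	173	152	155	164	72	61	40	56	41	35	78	32	59	21	65	49	53	33	47	40	15	14	24	11	21	17	14	16	20	33	57	63	60	66	34	71	54	71	82	36	65	32	36	38	66	36	40	36	56	89	28	50
mir027	416	305	386	400	303	2999	1530	2310	1767	2072	2082	2054	16720	9033	10770	16283	7659	12040	8162	12925	12455	12786	11073	8117	8661	13973	10933	8969	10319	13793	13382	10939	11194	10485	11313	15163	14395	11455	12563	12196	13167	11808	10618	7112	9213	9058	6167	16720	13633	15616	5754	16320
mir028	164	122	137	76	94	129	81	150	61	78	149	141	127	72	257	79	105	124	107	53	61	89	203	127	91	102	135	46	66	103	133	108	88	136	95	196	149	132	144	121	82	116	62	72	115	60	128	150	127	123	69	96
mir029	299	264	324	302	257	42	39	100	65	70	41	47	19	26	46	20	15	27	21	24	19	27	7	10	16	34	21	21	17	36	41	13	19	23	14	23	18	22	31	40	25	7	31	20	29	14	18	24	23	29	27	12
mir030	165	91	101	168	228	100	92	122	103	121	83	142	186	96	158	170	104	195	80	104	103	168	107	91	79	177	122	123	147	167	198	103	138	171	111	112	143	153	162	196	247	98	98	104	108	176	97	125	153	84	148	133
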
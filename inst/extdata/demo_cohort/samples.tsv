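sample_id	trimester	gestational_days	fetal_sex	group	birth_weight	birth_length	head_circumference	chest_circumference	placental_weight	pe_diagnosis	gd_diagnosis
S01_T1	1	74	XX	T1	NA	NA	NA	NA	NA	NA	NA
S02_T1	1	67	XY	T1	NA	NA	NA	NA	NA	NA	NA
S03_T1	1	55	XX	T1	NA	NA	NA	NA	NA	NA	NA
S04_T1	1	73	XY	T1	NA	NA	NA	NA	NA	NA	NA
S05_T1	1	51	XX	T1	NA	NA	NA	NA	NA	NA	NA
S06_T2	2	138	XY	T2	NA	NA	NA	NA	NA	NA	NA
S07_T2	2	128	XX	T2	NA	NA	NA	NA	NA	NA	NA
S08_T2	2	136	XY	T2	NA	NA	NA	NA	NA	NA	NA
S09_T2	2	109	XX	T2	NA	NA	NA	NA	NA	NA	NA
S10_T2	2	137	XY	T2	NA	NA	NA	NA	NA	NA	NA
S11_T2	2	138	XX	T2	NA	NA	NA	NA	NA	NA	NA
S12_T2	2	126	XY	T2	NA	NA	NA	NA	NA	NA	NA
S13_NORM	term	277	XX	NORM	3007.2	52.6	35.7	36	542.6	0	0
S14_NORM	term	281	XY	NORM	3770.6	54.3	36.2	33.7	576.2	0	0
S15_NORM	term	277	XX	NORM	4061.2	53.6	36.3	37.8	583.6	0	0
S16_NORM	term	276	XY	NORM	4436.8	51	37.4	35.5	473.3	0	0
S17_NORM	term	285	XX	NORM	3468.6	51.6	34.9	33.7	381.3	0	0
S18_NORM	term	289	XY	NORM	3662	51.1	36.2	35	681.8	0	0
S19_NORM	term	283	XX	NORM	4108	53.2	35.4	35.3	563.8	0	0
S20_NORM	term	273	XY	NORM	3782.6	51.7	36.6	36.4	394.7	0	0
S21_PE	term	267	XX	PE	3014.3	48.1	32	32.1	589.5	1	0
S22_PE	term	281	XY	PE	2897	44.3	33.3	31.1	544.8	1	0
S23_PE	term	282	XX	PE	2983.6	47.9	32.5	32.1	426.9	1	0
S24_PE	term	280	XY	PE	3076.7	50.7	31.6	30.4	377.9	1	0
S25_PE	term	291	XX	PE	2614.8	47.6	35	29.8	456.1	1	0
S26_PE	term	291	XY	PE	3154.8	47.9	35.2	28.9	476.6	1	0
S27_PE	term	286	XX	PE	2782.4	46.4	36.4	29	455.4	1	0
S28_PE	term	272	XY	PE	2838.6	47.4	32.5	29	577.5	1	0
S29_GD	term	289	XX	GD	4244.3	52.3	35.7	36	685.1	0	1
S30_GD	term	288	XY	GD	4126.2	50.5	36.4	36.5	697.2	0	1
S31_GD	term	278	XX	GD	3760.9	53.1	36	34.8	553.1	0	1
S32_GD	term	278	XY	GD	4233.3	52.9	35.2	36.7	534.8	0	1
S33_GD	term	268	XX	GD	4788.4	55.2	38	33.1	665.5	0	1
S34_GD	term	268	XY	GD	4256.7	51.3	35.4	37.6	512.9	0	1
S35_GD	term	265	XX	GD	4237.8	54.3	35.1	33.7	484.9	0	1
S36_GD	term	285	XY	GD	4432.2	52.8	36.3	35	479.4	0	1
S37_SGA	term	287	XX	SGA	2283.8	46.5	34	31	365.7	0	0
S38_SGA	term	263	XY	SGA	2241.1	46.8	32.6	29.4	440.3	0	0
S39_SGA	term	266	XX	SGA	2762.9	47.8	32.2	32	454.9	0	0
S40_SGA	term	287	XY	SGA	2884.7	46.5	32.5	29.1	457.4	0	0
S41_SGA	term	267	XX	SGA	2677.7	45.1	32.5	32.5	428.6	0	0
S42_SGA	term	289	XY	SGA	2279.4	44.3	29.7	33.4	396.2	0	0
S43_SGA	term	285	XX	SGA	2686.7	45.4	32.2	30.5	518.8	0	0
S44_SGA	term	262	XY	SGA	2835.1	45.8	33.1	31.2	436.3	0	0
S45_LGA	term	285	XX	LGA	4580.9	52.4	36.7	37.2	846.3	0	0
S46_LGA	term	267	XY	LGA	3655.5	52.2	37.6	36.8	872.9	0	0
S47_LGA	term	285	XX	LGA	4852.9	54.7	37.6	37.9	854.8	0	0
S48_LGA	term	278	XY	LGA	5223.5	55.4	36.4	32.2	899.1	0	0
S49_LGA	term	271	XX	LGA	4743.9	53.9	38.2	37	787.7	0	0
S50_LGA	term	269	XY	LGA	4670.8	55.5	39.5	37.7	752.5	0	0
S51_LGA	term	265	XX	LGA	4444.7	53.3	40	41	847.8	0	0
S52_LGA	term	286	XY	LGA	5105.6	52.9	38.4	37.6	874.1	0	0
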
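qtl	trait	envs	n_env	chrom	flank_left	flank_right	ci_start_mb	ci_end_mb	length_mb	lod	pve	add
qPH1-1	PH	E1,E2	2	chr1	mk328	mk336	161.10	169.60	8.5	6.42	7.44	10.49
qPH1-2	PH	E3	1	chr1	mk271	mk280	91.00	98.40	6.3	10.63	12.01	13.98
qPH2	PH	E1,E2,E3	3	chr2	mk926	mk950	193.10	201.40	8.3	5.31	5.91	9.22
qPH4	PH	E3	1	chr4	mk1569	mk1610	3.20	16.20	13.35	8.95	2.6	6.51
qPH5-1	PH	E2	1	chr5	mk2112	mk2119	22.70	29.10	5.75	7.4	4.13	8.64
qPH5-2	PH	E3	1	chr5	mk2312	mk2433	175.20	207.50	32.05	3.53	4.23	8.32
qPH8	PH	E1,E2	2	chr8	mk3521	mk3550	166.00	170.20	4.2	3.58	3.81	-7.09
qPH10	PH	E1,E2,E3	3	chr10	mk4016	mk4026	81.30	85.10	3.8	9.09	9.35	11.93
qEH1-1	EH	E1,E2	2	chr1	mk271	mk280	91.00	98.40	6.3	8.72	9.96	7.16
qEH1-2	EH	E3	1	chr1	mk309	mk314	146.50	154.90	6.85	14.63	15.68	8.75
qEH3	EH	E2,E3	2	chr3	mk1278	mk1284	138.70	145.30	5.9	3.68	3.43	-4.58
qEH5	EH	E3	1	chr5	mk2302	mk2320	172.90	178.60	5.45	3.98	3.9	4.28
qEH6-1	EH	E2	1	chr6	mk2598	mk2610	95.30	101.10	5.45	4.62	4.78	5.75
qEH6-2	EH	E3	1	chr6	mk2541	mk2549	60.90	72.20	7.4	4.23	4.16	4.59
qEH7	EH	E1	1	chr7	mk3037	mk3044	133.00	137.60	4.25	6.15	6.26	4.73
qEH8-1	EH	E2	1	chr8	mk3401	mk3531	120.30	167.40	46.9	3.68	3.92	-5.17
qEH10	EH	E1,E2,E3	3	chr10	mk4012	mk4037	80.10	94.70	14.6	9.99	9.9	7.14
qIN1	IN	E2	1	chr1	mk271	mk295	91.00	111.70	19.4	6.26	6.48	0.61
qIN3	IN	E1	1	chr3	mk1339	mk1357	167.60	173.00	5.25	6.54	8.11	-0.52
qIN8-1	IN	E1,E2	2	chr8	mk3405	mk3412	121.90	127.40	5.5	13.08	15.53	-0.83
qIN8-2	IN	E3	1	chr8	mk3371	mk3382	106.30	112.50	5.9	12.5	18.73	-0.91
qIN10	IN	E2,E3	2	chr10	mk4016	mk4036	81.30	94.20	12.9	11.11	13.66	0.84
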
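chrom	n_markers	phys_mb	length_cm	avg_spacing_cm	n_gaps_lt5	max_gap_cm
chr1	738	301.43	239.48	0.32	738	4.81
chr2	337	237.89	151.46	0.45	336	4.93
chr3	476	232.23	163.33	0.34	474	5.57
chr4	447	242.03	163.22	0.37	445	6.51
chr5	487	217.93	170.86	0.35	486	2.52
chr6	346	169.38	120.38	0.35	344	5.11
chr7	395	176.81	143.24	0.36	394	2.94
chr8	358	175.35	142.66	0.4	357	2.96
chr9	323	157.02	122.05	0.38	321	11.15
chr10	276	149.63	128.97	0.47	274	5.11
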
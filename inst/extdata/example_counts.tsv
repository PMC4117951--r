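sim_1	1	+	CpG	0	9
sim_1	61	+	CpG	0	2
sim_1	121	+	CpG	0	2
sim_1	181	+	CpG	0	5
sim_1	241	+	CpG	0	5
sim_1	301	+	CpG	0	8
sim_1	361	+	CpG	0	4
sim_1	421	+	CpG	0	18
sim_1	481	+	CpG	0	1
sim_1	541	+	CpG	0	1
sim_1	601	+	CpG	0	6
sim_1	661	+	CpG	1	2
sim_1	721	+	CpG	8	9
sim_1	781	+	CpG	0	6
sim_1	841	+	CpG	0	2
sim_1	901	+	CpG	0	1
sim_1	961	+	CpG	0	1
sim_1	1021	+	CpG	0	1
sim_1	1081	+	CpG	0	3
sim_1	1141	+	CpG	0	2
sim_1	1201	+	CpG	0	6
sim_1	1261	+	CpG	0	4
sim_1	1321	+	CpG	0	2
sim_1	1381	+	CpG	0	5
sim_1	1441	+	CpG	0	3
sim_1	1501	+	CpG	0	14
sim_1	1561	+	CpG	0	3
sim_1	1621	+	CpG	0	7
sim_1	1681	+	CpG	0	1
sim_1	1741	+	CpG	0	1
sim_1	1801	+	CpG	0	4
sim_1	1861	+	CpG	0	1
sim_1	1921	+	CpG	0	3
sim_1	1981	+	CpG	0	1
sim_1	2041	+	CpG	0	7
sim_1	2101	+	CpG	0	15
sim_1	2161	+	CpG	0	11
sim_1	2221	+	CpG	0	4
sim_1	2281	+	CpG	0	5
sim_1	2341	+	CpG	0	3
sim_1	2401	+	CpG	0	1
sim_1	2461	+	CpG	0	9
sim_1	2521	+	CpG	0	4
sim_1	2581	+	CpG	0	2
sim_1	2641	+	CpG	0	4
sim_1	2701	+	CpG	0	7
sim_1	2761	+	CpG	0	4
sim_1	2821	+	CpG	0	5
sim_1	2881	+	CpG	0	1
sim_1	2941	+	CpG	0	2
sim_1	3001	+	CpG	0	1
sim_1	3061	+	CpG	0	2
sim_1	3121	+	CpG	0	5
sim_1	3181	+	CpG	0	2
sim_1	3241	+	CpG	17	23
sim_1	3301	+	CpG	0	12
sim_1	3361	+	CpG	1	1
sim_1	3421	+	CpG	0	9
sim_1	3481	+	CpG	0	10
sim_1	3541	+	CpG	1	18
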
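condition	model	cohort_n	cases	low_n	low_cases	advised_n	advised_cases
cad_women	frs	21969	167	7426	22	5680	99
cad_men	frs	14944	333	5171	55	4431	165
cad	prs	36913	500	25839	173	3692	165
cad	rules	36913	500	1521	0	14980	360
t2d	frs	42978	1005	12305	39	12634	726
t2d	prs	42978	1005	30084	467	4298	239
t2d	rules	42978	1005	8351	13	14169	819
htn	frs	33541	2379	3359	23	26587	2317
htn	prs	33541	2379	23479	1327	3354	391
htn	rules	33541	2379	2274	17	12506	1759
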
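condition	cohort_n	cases	ev_up	ev_down	ev_same_high	ev_same_low	ne_up	ne_down	ne_same_high	ne_same_low
cad_women	21969	167	35	17	82	33	4010	1835	3746	12211
cad_men	14944	333	118	40	125	50	4306	1708	2558	6039
t2d	42978	1005	202	109	617	77	7167	5725	6183	22898
htn	33541	2379	8	566	1751	54	270	13793	10477	6622
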
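rbc_pct	a414	degree_printed
0	0.143
0.008	0.184	1.29
0.016	0.245	1.73
0.031	0.321	2.28
0.0625	0.420	2.96
0.125	0.626	4.39
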
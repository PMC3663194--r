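sample_id	subject_id	condition	pair_id	a414	rbc_fraction
d1	donor	dilution		0.143	0
d2	donor	dilution		0.184	0.008
d3	donor	dilution		0.245	0.016
d4	donor	dilution		0.321	0.031
d5	donor	dilution		0.420	0.0625
d6	donor	dilution		0.626	0.125
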
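pair_id	a414_non_hemolyzed	a414_hemolyzed	degree_printed
N1	0.174	0.413	2.36
N2	0.153	0.412	2.68
MPM1	0.124	0.558	4.53
CAD1	0.184	0.25	1.37
CAD2	0.127	0.242	1.90
CAD3	0.143	0.574	4.01
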
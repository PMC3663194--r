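mir_id	d1	d2	d3	d4	d5	d6
miR-1274B	24.73	25.00	24.94	24.70	24.65	24.82
miR-142-3p	24.33	24.55	24.34	23.86	23.65	23.55
miR-146a	25.82	26.02	26.01	25.84	25.80	26.00
miR-122	28.28	28.59	28.78	28.18	28.29	28.63
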
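A	C	G	T
0.15	0.15	0.55	0.15
0.066667	0.799999	0.066667	0.066667
0.900001	0.033333	0.033333	0.033333
0.023333	0.930001	0.023333	0.023333
0.15	0.55	0.15	0.15
0.88	0.04	0.04	0.04
0.023333	0.023333	0.930001	0.023333
0.06	0.06	0.82	0.06
0.083333	0.083333	0.083333	0.750001
0.033333	0.033333	0.900001	0.033333
0.023333	0.023333	0.930001	0.023333
0.116667	0.649999	0.116667	0.116667
0.15	0.15	0.55	0.15
0.349999	0.216667	0.216667	0.216667
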
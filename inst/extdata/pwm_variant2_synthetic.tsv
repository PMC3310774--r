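A	C	G	T
0.116667	0.649999	0.116667	0.116667
0.06	0.82	0.06	0.06
0.900001	0.033333	0.033333	0.033333
0.026667	0.919999	0.026667	0.026667
0.166667	0.166667	0.166667	0.499999
0.85	0.05	0.05	0.05
0.033333	0.033333	0.900001	0.033333
0.799999	0.066667	0.066667	0.066667
0.093333	0.093333	0.093333	0.720001
0.04	0.04	0.88	0.04
0.026667	0.026667	0.919999	0.026667
0.106667	0.679999	0.106667	0.106667
0.166667	0.166667	0.499999	0.166667
0.206667	0.379999	0.206667	0.206667
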
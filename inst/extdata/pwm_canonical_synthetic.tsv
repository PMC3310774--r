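A	C	G	T
0.1	0.7	0.1	0.1
0.05	0.85	0.05	0.05
0.919999	0.026667	0.026667	0.026667
0.016667	0.949999	0.016667	0.016667
0.133333	0.600001	0.133333	0.133333
0.900001	0.033333	0.033333	0.033333
0.016667	0.016667	0.949999	0.016667
0.05	0.05	0.85	0.05
0.066667	0.066667	0.066667	0.799999
0.026667	0.026667	0.919999	0.026667
0.016667	0.016667	0.949999	0.016667
0.1	0.7	0.1	0.1
0.133333	0.133333	0.600001	0.133333
0.2	0.4	0.2	0.2
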
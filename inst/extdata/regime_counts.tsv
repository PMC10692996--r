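regime	lines	mutations	mutations_mean	mutations_se	callable_sites	generations	transitions	transversions
YoungT1	6	12	2.00	0.58	90566554	3	12	0
PeakT2	6	5	0.83	0.48	93817854	3	5	0
OldT5	6	20	3.33	1.82	92742405	3	19	1
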
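id	t1	t2	t3	t4	t5
d1	1	0	0	0	0
d2	1	1	0	0	0
d3	0	1	1	0	0
d4	0	0	0	1	1
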
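id	t1	t2	t3	t4	t5
t1	1	0.9	0.85	0.1	0.05
t2	0.9	1	0.8	0.15	0.1
t3	0.85	0.8	1	0.1	0.1
t4	0.1	0.15	0.1	1	0.9
t5	0.05	0.1	0.1	0.9	1
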
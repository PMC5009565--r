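id	d1	d2	d3	d4
d1	1	0.85	0.8	0.1
d2	0.85	1	0.75	0.15
d3	0.8	0.75	1	0.2
d4	0.1	0.15	0.2	1
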
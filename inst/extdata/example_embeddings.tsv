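token	d1	d2	d3
You	0.12	-0.98	1.41
know	-0.55	0.23	0.77
my	1.02	0.34	-0.12
methods	-0.31	-0.44	0.25
Watson	0.88	1.21	-0.67
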
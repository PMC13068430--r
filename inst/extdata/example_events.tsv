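token	onset	offset	pos	top1	top5
You	0.00	0.42	function	FALSE	FALSE
know	0.42	0.81	content	TRUE	TRUE
my	0.81	1.05	function	FALSE	TRUE
methods	1.05	1.71	content	FALSE	FALSE
Watson	1.71	2.30	content	TRUE	TRUE
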
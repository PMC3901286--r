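place	invertase	hexokinase	fructokinase	PGI_f	PGI_b	glycolysis	starch_synthase	sucrose_input	starch_output
sucrose	-1	0	0	0	0	0	0	1	0
glucose	1	-1	0	0	0	0	0	0	0
fructose	1	0	-1	0	0	0	0	0	0
F6P	0	0	1	1	-1	-1	0	0	0
G6P	0	1	0	-1	1	0	-1	0	0
starch	0	0	0	0	0	0	1	0	-1
ADP	0	1	1	0	0	-29	1	0	0
ATP	0	-1	-1	0	0	29	-1	0	0
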
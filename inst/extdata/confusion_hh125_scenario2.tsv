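class	Cook Lunch	Eat Lunch	Personal Hygiene
Cook Lunch	64	0	0
Eat Lunch	0	1	0
Personal Hygiene	0	6	219
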
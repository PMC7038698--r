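class	Cook Lunch	Eat Lunch	Personal Hygiene
Cook Lunch	13	0	0
Eat Lunch	0	14	0
Personal Hygiene	4	0	154
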
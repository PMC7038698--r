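class	Relax	Sleep	Toilet
Relax	84	0	0
Sleep	7	79	0
Toilet	0	97	352
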
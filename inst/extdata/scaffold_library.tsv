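family	cys_count	min_len	max_len
CHH	6	71	73
MIH/GIH	6	74	74
Eclosion hormone	6	55	57
CFSH	10	200	280
Neuroparsin	12	90	105
Bursicon	10	80	95
Bursicon	11	80	95
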
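family	term	generic
Allatostatins	allatostatin	FALSE
Allatostatins	prohormone-1	FALSE
Bursicon	bursicon	FALSE
Corazonin	corazonin	FALSE
CCAP	cardioactive	FALSE
CHH	hyperglycemic	FALSE
MIH/GIH	molt-inhibiting	FALSE
MIH/GIH	gonad-inhibiting	FALSE
MIH/GIH	vitellogenesis inhibiting	FALSE
MIH/GIH	MIH/GIH	FALSE
CFSH	female sex hormon	FALSE
DH	diuretic	FALSE
Eclosion hormone	eclosion	FALSE
Myosuppressin	myosuppressin	FALSE
Myosuppressin	myosupressin	FALSE
Follistatin	follistatin	FALSE
Myostatin	myostatin	FALSE
Myostatin	MSTN	FALSE
NPY	neuropeptide Y	FALSE
NPY	prepro-NPF	FALSE
Neuroparsin	neuroparsin	FALSE
Orcokinin	orcokinin	FALSE
PDH	pigment dispersing	FALSE
Prohormone-3	prohormone-3	FALSE
Prohormone-4	prohormone-4	FALSE
RPCH	red pigment concentrating	FALSE
RPCH	pigment-concentrating	FALSE
Sulfakinin	sulfakinin	FALSE
Tachykinin	tachykinin	FALSE
unassigned_hormone	hormone	TRUE
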
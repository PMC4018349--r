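family	pattern	requires_amidation	min_len	max_len	cys_count	scope
AST-A	Y.FG[LIV]$	TRUE	5	20	NA	peptide
AST-B	W.{6}W$	TRUE	8	16	NA	peptide
AST-C/prohormone-1	QC.FN..SCF	FALSE	10	20	NA	peptide
Orcokinin	^NFDEID	FALSE	8	16	NA	peptide
Tachykinin	F.G.R$	TRUE	6	12	NA	peptide
Sulfakinin	GH[ML]RF$	TRUE	8	16	NA	peptide
Myosuppressin	RF$	TRUE	10	10	NA	peptide
Corazonin	^Q?TFQYSRGWTN$	TRUE	10	11	NA	peptide
RPCH	W$	TRUE	8	8	NA	peptide
CCAP	.	TRUE	8	10	2	peptide
PDH	.	TRUE	18	18	0	peptide
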
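family	peptide	amidated	best_hit	accession	identity_note
Allatostatin A	HNNYAFGL	TRUE	allatostatin precursor protein [Panulirus interruptus]	BAF64528	100% identity
Allatostatin A	TPDYAFGL	TRUE	allatostatin precursor protein [Panulirus interruptus]	BAF64528	100% identity
Allatostatin A	EGMYSFGL	TRUE	allatostatin precursor protein [Panulirus interruptus]	BAF64528	DGMYSFGLa
Allatostatin A	ADLFSFGL	TRUE	allatostatin precursor protein [Panulirus interruptus]	BAF64528	100% identity
Allatostatin A	SGNYNFGL	TRUE	allatostatin precursor protein [Panulirus interruptus]	BAF64528	100% identity
Allatostatin A	SQYAFGL	TRUE	A-type allatostatin [Amphibalanus amphitrite]	AFK81929	100% identity
Allatostatin A	SKLYSFGL	TRUE	FGLa-related allatostatin [Nilaparvata lugens]	BAO00953	QKLYSFGLa
Allatostatin A	NRQYSFGL	TRUE	allatostatin precursor protein [Panulirus interruptus]	BAF64528	100% identity
Allatostatin A	SQQYAFGL	TRUE	type-a prepro-allatostatin [Macrobrachium nipponense]	AEX86939	100% identity
Allatostatin A	PRNYAFGL	TRUE	allatostatin precursor protein [Panulirus interruptus]	BAF64528	100% identity
Allatostatin A	PTAYSFGL	TRUE	allatostatin precursor protein [Panulirus interruptus]	BAF64528	PTTYSFGLa
Allatostatin A	TASYGFGL	TRUE	allatostatin precursor protein [Panulirus interruptus]	BAF64528	100% identity
Allatostatin A	SDLYDNDLGRSYDFGL	FALSE	allatostatin precursor protein [Panulirus interruptus]	BAF64528	SDSYDNGLGRRSYDFGL
Allatostatin A	SGPYAFGL	TRUE	allatostatin precursor protein [Panulirus interruptus]	BAF64528	100% identity
Allatostatin A	GGPYAFGL	TRUE	type-a pre-proallatostatin [Macrobrachium rosenbergii]	AAY82901	100% identity
Allatostatin A	ADLYSFGL	TRUE	allatostatin precursor protein [Panulirus interruptus]	BAF64528	100% identity
Allatostatin A	ADPYSFGL	TRUE	allatostatin precursor protein [Panulirus interruptus]	BAF64528	100% identity
Allatostatin A	AGQYSFGL	TRUE	allatostatin precursor protein [Panulirus interruptus]	BAF64528	100% identity
Allatostatin A	AGPYSFGL	TRUE	allatostatin precursor protein [Panulirus interruptus]	BAF64528	100% identity
Allatostatin A	EDSPASDAYTL	FALSE	allatostatin precursor protein [Panulirus interruptus]	BAF64528	EDSSASDPYIL
Allatostatin A	SGSYSFGL	TRUE	type-a prepro-allatostatin [Macrobrachium nipponense]	AEX86939	100% identity
Allatostatin A	AGPYSFGL	TRUE	allatostatin precursor protein [Panulirus interruptus]	BAF64528	100% identity
Allatostatin B	TDWSSMHGTW	TRUE	B-type preproallatostatin II [Pandalopsis japonica]	AFV91539	ADWSSMRGTWa
Allatostatin B	PDLLQAPLQAVGD	FALSE	Na		
Allatostatin B	GNWDKFHGSW	TRUE	B-type preproallatostatin II [Pandalopsis japonica]	AFV91539	ANWNKFQGSWa
Allatostatin B	AEEIQAAED	FALSE	Na		
Allatostatin B	ADWNKFHGSW	TRUE	Na		
Allatostatin B	GDEFASPELETTED	FALSE	Na		
Allatostatin B	ANWNKFHGSW	TRUE	B-type preproallatostatin II [Pandalopsis japonica]	AFV91539	ANWNKFQGSWa
Allatostatin B	GDDLVDAEL	FALSE	Na		
Allatostatin B	DWSSLQGTW	TRUE	B-type preproallatostatin I, partial [Pandalopsis japonica]	AFV91539	GWSSLQGSWa
Allatostatin B	DWNNLHGAW	TRUE	B-type preproallatostatin I, partial [Pandalopsis japonica]	AFV91539	AWKNLHGAWa
Allatostatin B	SPDWNSLRGAW	TRUE	B-type preproallatostatin I, partial [Pandalopsis japonica]	AFV91539	SGDWNSLRGAWa
Allatostatin B	APDWAQFRGSW	TRUE	B-type preproallatostatin I, partial [Pandalopsis japonica]	AFV91539	DGDWSQFRGSWa
Allatostatin B	VPDEVNETAAHQA	FALSE	Na		
Allatostatin C	ALGEEQLQEEAAKS	FALSE	Na		
Allatostatin C	MFAPLSGLPGELPTI	FALSE	C-type preproallatostatin [Pandalopsis japonica]	AFV91540	LFAPLSGLPGEIPTM
Allatostatin C	QIRYHQCYFNPISCF	FALSE	C-type preproallatostatin [Pandalopsis japonica]	AFV91540	QIRYRQCYFNPISCF
Hormone-1	SYWKQCAFNAVSCF	TRUE	prohormone-1 isoform X2 [Apis mellifera]	XP_006570429	100% identity
Corazonin	TFQYSRGWTN	TRUE	Pro-corazonin [Harpegnathos saltator]	EFN88292	100% identity
Orcokinin	FDAFTTGFGHSKR	FALSE	Orcokinin [Procambarus clarkii]	Q9NL83	100% identity
Orcokinin	NFDEIDRSGFAFAKK	FALSE	Orcokinin [Procambarus clarkii]	Q9NL83	NFDEIDRSGFGFAKK
Orcokinin	NFDEIDRAGLGFAKR	FALSE	prepro-orcokinin II [Homarus americanus]	ACD13197	NFDEIDRSGFGFNKR
Orcokinin	NFDEIDRSGFGFNKR	FALSE	prepro-orcokinin II [Homarus americanus]	ACD13197	100% identity
Orcokinin	NFDEIDRAGLGFHKR	FALSE	prepro-orcokinin II [Homarus americanus]	ACD13197	NFDEIDRSGFGFHKR
Orcokinin	NFDEIDRSGFGFNKR	FALSE	prepro-orcokinin II [Homarus americanus]	ACD13197	100% identity
Orcokinin	NFDEIDRTGFGFHKR	FALSE	Orcokinin [Procambarus clarkii]	Q9NL83	100% identity
Orcokinin	DYDGVYPDKR	FALSE	prepro-orcokinin II [Homarus americanus]	ACD13197	DYD-VYPEKR
Orcokinin	NFDEIDRAGFGFVKR	FALSE	prepro-orcokinin II [Homarus americanus]	ACD13197	NFDEIDRSGFGFVKR
Orcokinin	AFGPRDISNLYKR	FALSE	prepro-orcokinin II [Homarus americanus]	ACD13197	VYGPRDIANLYKR
Orcokinin	NFDEIDRSGFGFVRR	FALSE	prepro-orcokinin II [Homarus americanus]	ACD13197	100% identity
PDH	NAELINSILGLPKVMNDA	TRUE	Pigment-dispersing hormone [Uca pugilator]	P08871	NSELINSILGLPKVMNDAa
PDH	NAELINSLLGIPKVMSDA	TRUE	Pigment-dispersing hormone [Litopenaeus vannamei]	P91963	NSELINSLLGIPKVMNDAa
Sulfakinin	EFDEYGHMRF	TRUE	preprosulfakinin [Homarus americanus]	ABQ95346	100% identity
Sulfakinin	SGGEYDDYGHLRF	TRUE	preprosulfakinin [Homarus americanus]	ABQ95346	GGGEYDDYGHLRFa
Tachykinin	APSGFLGMR	TRUE	preprotachykinin [Procambarus clarkii]	BAC82426	100% identity
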
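id	preferred_name	synonyms	namespace
CYP4A11	CYP4A11	cytochrome P450 4A11	HGNC
CD40LG	CD40LG	CD154|CD40 ligand	HGNC
CD40	CD40		HGNC
MMP9	MMP9	matrix metallopeptidase 9|gelatinase B	HGNC
MMP2	MMP2	matrix metallopeptidase 2	HGNC
MMP12	MMP12		HGNC
TIMP1	TIMP1	tissue inhibitor of metalloproteinase 1	HGNC
TIMP2	TIMP2		HGNC
VEGFA	VEGFA	vascular endothelial growth factor A	HGNC
FGF2	FGF2	basic fibroblast growth factor	HGNC
HMGB1	HMGB1	high mobility group box 1	HGNC
THBS1	THBS1	thrombospondin 1	HGNC
COL1A1	COL1A1	collagen type I alpha 1	HGNC
COL4A3	COL4A3		HGNC
ABL1	ABL1		HGNC
ETS2	ETS2		HGNC
CCL2	CCL2	MCP-1|monocyte chemoattractant protein 1	HGNC
CCL5	CCL5	RANTES	HGNC
CCR2	CCR2		HGNC
CXCL12	CXCL12		HGNC
ICAM1	ICAM1	intercellular adhesion molecule 1	HGNC
VCAM1	VCAM1	vascular cell adhesion molecule 1	HGNC
SELE	SELE	E-selectin	HGNC
SELP	SELP	P-selectin	HGNC
PECAM1	PECAM1		HGNC
IL1B	IL1B	interleukin 1 beta	HGNC
IL6	IL6	interleukin 6	HGNC
IL10	IL10	interleukin 10	HGNC
IL18	IL18		HGNC
TNF	TNF	tumor necrosis factor alpha	HGNC
IFNG	IFNG	interferon gamma	HGNC
TGFB1	TGFB1	transforming growth factor beta 1	HGNC
PDGFB	PDGFB		HGNC
EGFR	EGFR		HGNC
NOS3	NOS3	endothelial nitric oxide synthase	HGNC
NOS2	NOS2		HGNC
PTGS2	PTGS2	cyclooxygenase 2	HGNC
ALOX5	ALOX5		HGNC
LDLR	LDLR	low density lipoprotein receptor	HGNC
SCARB1	SCARB1		HGNC
CD36	CD36		HGNC
MSR1	MSR1		HGNC
ABCA1	ABCA1		HGNC
PPARG	PPARG		HGNC
PPARA	PPARA		HGNC
NFKB1	NFKB1		HGNC
RELA	RELA		HGNC
TP53	TP53		HGNC
MYC	MYC		HGNC
FN1	FN1	fibronectin 1	HGNC
ELN	ELN	elastin	HGNC
ACTA2	ACTA2	smooth muscle alpha actin	HGNC
MYH11	MYH11		HGNC
CNN1	CNN1	calponin 1	HGNC
SPP1	SPP1	osteopontin	HGNC
LGALS3	LGALS3	galectin-3	HGNC
F3	F3	tissue factor	HGNC
SERPINE1	SERPINE1	PAI-1	HGNC
PLAT	PLAT		HGNC
PLAU	PLAU		HGNC
PLG	PLG	plasminogen	HGNC
FGA	FGA		HGNC
VWF	VWF	von Willebrand factor	HGNC
ITGB3	ITGB3		HGNC
ITGAM	ITGAM		HGNC
CD68	CD68		HGNC
CD4	CD4		HGNC
CD8A	CD8A		HGNC
FOXP3	FOXP3		HGNC
TBX21	TBX21		HGNC
GATA3	GATA3		HGNC
CASP3	CASP3	caspase 3	HGNC
CASP1	CASP1		HGNC
BAX	BAX		HGNC
BCL2	BCL2		HGNC
FAS	FAS		HGNC
FASLG	FASLG	Fas ligand	HGNC
HIF1A	HIF1A		HGNC
EPAS1	EPAS1		HGNC
AGT	AGT	angiotensinogen	HGNC
AGTR1	AGTR1	AT-1 receptor	HGNC
ACE	ACE	angiotensin converting enzyme	HGNC
REN	REN	renin	HGNC
EDN1	EDN1	endothelin 1	HGNC
NPPB	NPPB		HGNC
CRP	CRP	C-reactive protein	HGNC
SAA1	SAA1		HGNC
HP	HP	haptoglobin	HGNC
APOB	APOB	apolipoprotein B	HGNC
APOA1	APOA1	apolipoprotein A-I	HGNC
LPL	LPL	lipoprotein lipase	HGNC
CETP	CETP		HGNC
PON1	PON1	paraoxonase 1	HGNC
MPO	MPO	myeloperoxidase	HGNC
NOX4	NOX4		HGNC
CYBB	CYBB		HGNC
SOD1	SOD1	superoxide dismutase 1	HGNC
CAT	CAT	catalase	HGNC
GPX1	GPX1	glutathione peroxidase 1	HGNC
HMOX1	HMOX1	heme oxygenase 1	HGNC
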
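id	preferred_name	synonyms	namespace
20-HETE	20-HETE	20-hydroxyeicosatetraenoic acid	CHEBI
cholesterol	cholesterol		CHEBI
oxidized low-density lipoprotein	oxidized low-density lipoprotein	oxLDL	CHEBI
low-density lipoprotein	low-density lipoprotein		CHEBI
high-density lipoprotein	high-density lipoprotein		CHEBI
triglyceride	triglyceride	triacylglycerol	CHEBI
7-ketocholesterol	7-ketocholesterol		CHEBI
lysophosphatidylcholine	lysophosphatidylcholine		CHEBI
arachidonic acid	arachidonic acid		CHEBI
prostaglandin E2	prostaglandin E2	PGE2	CHEBI
thromboxane A2	thromboxane A2	TXA2	CHEBI
leukotriene B4	leukotriene B4	LTB4	CHEBI
nitric oxide	nitric oxide		CHEBI
superoxide anion	superoxide anion		CHEBI
hydrogen peroxide	hydrogen peroxide		CHEBI
peroxynitrite	peroxynitrite		CHEBI
angiotensin II	angiotensin II		CHEBI
homocysteine	homocysteine		CHEBI
glucose	glucose		CHEBI
insulin	insulin		CHEBI
ceramide	ceramide		CHEBI
sphingosine 1-phosphate	sphingosine 1-phosphate	S1P	CHEBI
retinoic acid	retinoic acid		CHEBI
vitamin D3	vitamin D3	cholecalciferol	CHEBI
alpha-tocopherol	alpha-tocopherol		CHEBI
ascorbic acid	ascorbic acid		CHEBI
simvastatin	simvastatin		CHEBI
atorvastatin	atorvastatin		CHEBI
aspirin	aspirin	acetylsalicylic acid	CHEBI
clopidogrel	clopidogrel		CHEBI
heparin	heparin		CHEBI
warfarin	warfarin		CHEBI
nicotine	nicotine		CHEBI
palmitic acid	palmitic acid		CHEBI
oleic acid	oleic acid		CHEBI
linoleic acid	linoleic acid		CHEBI
eicosapentaenoic acid	eicosapentaenoic acid	EPA	CHEBI
docosahexaenoic acid	docosahexaenoic acid	DHA	CHEBI
sphingomyelin	sphingomyelin		CHEBI
phosphatidylserine	phosphatidylserine		CHEBI
uric acid	uric acid		CHEBI
bilirubin	bilirubin		CHEBI
hemin	hemin		CHEBI
serotonin	serotonin		CHEBI
histamine	histamine		CHEBI
adenosine	adenosine		CHEBI
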
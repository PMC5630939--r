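id	preferred_name	synonyms	namespace
angiogenesis	angiogenesis	microvessel density|neovascularization	GOBP
blood vessel development	blood vessel development		GOBP
chemotaxis	chemotaxis		GOBP
inflammatory response	inflammatory response		GOBP
immune response	immune response		GOBP
cell adhesion	cell adhesion		GOBP
leukocyte migration	leukocyte migration		GOBP
monocyte recruitment	monocyte recruitment		GOBP
macrophage activation	macrophage activation		GOBP
platelet aggregation	platelet aggregation		GOBP
platelet activation	platelet activation		GOBP
blood coagulation	blood coagulation		GOBP
fibrinolysis	fibrinolysis		GOBP
apoptotic process	apoptotic process	apoptosis	GOBP
necrotic cell death	necrotic cell death		GOBP
cell proliferation	cell proliferation		GOBP
smooth muscle cell migration	smooth muscle cell migration		GOBP
endothelial cell migration	endothelial cell migration		GOBP
vascular permeability	vascular permeability		GOBP
vasoconstriction	vasoconstriction		GOBP
vasodilation	vasodilation		GOBP
lipid storage	lipid storage		GOBP
cholesterol efflux	cholesterol efflux		GOBP
foam cell formation	foam cell formation		GOBP
lipoprotein oxidation	lipoprotein oxidation		GOBP
extracellular matrix disassembly	extracellular matrix disassembly		GOBP
extracellular matrix organization	extracellular matrix organization		GOBP
collagen catabolic process	collagen catabolic process		GOBP
elastin catabolic process	elastin catabolic process		GOBP
wound healing	wound healing		GOBP
response to oxidative stress	response to oxidative stress		GOBP
oxidative stress	oxidative stress		GOBP
nitric oxide biosynthetic process	nitric oxide biosynthetic process		GOBP
prostaglandin biosynthetic process	prostaglandin biosynthetic process		GOBP
cytokine production	cytokine production		GOBP
chemokine production	chemokine production		GOBP
T cell activation	T cell activation		GOBP
B cell activation	B cell activation		GOBP
antigen presentation	antigen presentation		GOBP
complement activation	complement activation		GOBP
phagocytosis	phagocytosis		GOBP
efferocytosis	efferocytosis		GOBP
autophagy	autophagy		GOBP
cellular senescence	cellular senescence		GOBP
calcification	calcification		GOBP
osteogenic differentiation	osteogenic differentiation		GOBP
angiotensin signaling	angiotensin signaling		GOBP
endothelial dysfunction	endothelial dysfunction		GOBP
plaque destabilization	plaque destabilization		GOBP
atherogenesis	atherogenesis		GOBP
neointima formation	neointima formation		GOBP
intimal thickening	intimal thickening		GOBP
hemorrhage	hemorrhage	intraplaque hemorrhage	GOBP
thrombosis	thrombosis		GOBP
fibrous cap thinning	fibrous cap thinning		GOBP
necrotic core expansion	necrotic core expansion		GOBP
monocyte adhesion	monocyte adhesion		GOBP
lymphocyte infiltration	lymphocyte infiltration		GOBP
mast cell degranulation	mast cell degranulation		GOBP
angiogenic sprouting	angiogenic sprouting		GOBP
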
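reaction	metabolites	genes	pathways
HEX1	glucose[c] // glucose-6-phosphate[c]	HXK1 // HXK2 // GLK1	glycolysis
PGI	glucose-6-phosphate[c] // fructose-6-phosphate[c]	PGI1	glycolysis
PFK	fructose-6-phosphate[c] // fructose-1,6-bisphosphate[c]	PFK1 // PFK2	glycolysis
FBA	fructose-1,6-bisphosphate[c] // glyceraldehyde-3-phosphate[c]	FBA1	glycolysis
GAPDH	glyceraldehyde-3-phosphate[c] // 1,3-bisphosphoglycerate[c]	TDH1 // TDH2 // TDH3	glycolysis
PYK	phosphoenolpyruvate[c] // pyruvate[c]	CDC19 // PYK2	glycolysis
ZWF	glucose-6-phosphate[c] // 6-phospho-glucono-1,5-lactone[c]	ZWF1	pentose phosphate pathway
GND	6-phosphogluconate[c] // ribulose-5-phosphate[c]	GND1 // GND2	pentose phosphate pathway
TKL	ribose-5-phosphate[c] // glyceraldehyde-3-phosphate[c]	TKL1 // TKL2	pentose phosphate pathway
TAL	sedoheptulose-7-phosphate[c] // fructose-6-phosphate[c]	TAL1	pentose phosphate pathway
CIT	oxaloacetate[m] // citrate[m]	CIT1 // CIT3	TCA cycle
ACO	citrate[m] // isocitrate[m]	ACO1	TCA cycle
IDH	isocitrate[m] // 2-ketoglutarate[m]	IDH1 // IDH2	TCA cycle
KGD	2-ketoglutarate[m] // succinyl-CoA[m]	KGD1 // KGD2	TCA cycle
MDH	malate[m] // oxaloacetate[m]	MDH1	TCA cycle
PYC	pyruvate[c] // oxaloacetate[m]	PYC1 // PYC2	anaplerosis
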
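mouse_symbol	human_symbol
Gfap	GFAP
Aqp4	AQP4
Aif1	AIF1
Rbfox3	RBFOX3
Slc17a7	SLC17A7
Gad1	GAD1
Mbp	MBP
Cldn5	CLDN5
Foxj1	FOXJ1
Pdgfrb	PDGFRB
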
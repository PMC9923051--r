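name	pattern
HinfI	GANTC
EcoRII	CCWGG
AluI	AGCT
HaeIII	GGCC
TaqI	TCGA
MseI	TTAA
NlaIII	CATG
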
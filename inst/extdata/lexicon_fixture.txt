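LOX
ACTB
actin
TP53
GAPDH
EGFR
MYC
KRAS
BRCA1
BRCA2
CDK2
CCND1
VEGFA
TNF
IL6
STAT3
AKT1
MTOR
PTEN
RB1
SMAD4
NOTCH1
WNT1
GSK3B
MAPK1
JUN
FOS
SRC
ABL1
BCL2
BAX
CASP3
PARP1
HSPA5
CDH1
VIM
SNAI1
TWIST1
ZEB1
KIT
PDGFRA
FLT3
JAK2
NRAS
HRAS
PIK3CA
SMAD2
TGFB1
NFKB1
SFN
protein
gel
factor
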
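# Het codes kept in the receptor during ligand stripping.
# Common organic cofactors and prosthetic groups; edit freely.
HEM
HEC
HEA
NAD
NAI
NAP
NDP
FAD
FDA
FMN
PLP
PMP
TPP
TDP
SAM
SAH
COA
ACO
GSH
BTN
B12
CLA
BCL
PQQ
H4B
BH4
MQ7
UQ1
UQ2
F43
MTE
MGD
SF4
FES
FE2
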
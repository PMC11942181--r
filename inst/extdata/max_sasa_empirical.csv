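# Empirical per-residue maximum SASA (nm^2): largest values observed for
# residue X in Gly-X-Gly stretches of real protein structures
# (Tien et al. 2013, PLoS ONE 8:e80635; converted from A^2).
residue,max_sasa_nm2
ALA,1.21
ARG,2.65
ASN,1.87
ASP,1.87
CYS,1.48
GLU,2.14
GLN,2.14
GLY,0.97
HIS,2.16
ILE,1.95
LEU,1.91
LYS,2.30
MET,2.03
PHE,2.28
PRO,1.54
SER,1.43
THR,1.63
TRP,2.64
TYR,2.55
VAL,1.65
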
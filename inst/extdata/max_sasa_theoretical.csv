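# Theoretical per-residue maximum SASA (nm^2): fully extended Gly-X-Gly
# tripeptides (Tien et al. 2013, PLoS ONE 8:e80635; converted from A^2).
residue,max_sasa_nm2
ALA,1.29
ARG,2.74
ASN,1.95
ASP,1.93
CYS,1.67
GLU,2.23
GLN,2.25
GLY,1.04
HIS,2.24
ILE,1.97
LEU,2.01
LYS,2.36
MET,2.24
PHE,2.40
PRO,1.59
SER,1.55
THR,1.72
TRP,2.85
TYR,2.63
VAL,1.74
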
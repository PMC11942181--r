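# label: ELP transition temperature Tt (degC) by guest residue
# orientation: NONE
# Template: fill the value column with per-guest transition temperatures
# from your experimental reference before running correlate_with_tt().
aa,value
A,NA
R,NA
N,NA
D,NA
C,NA
Q,NA
E,NA
G,NA
H,NA
I,NA
L,NA
K,NA
M,NA
F,NA
S,NA
T,NA
W,NA
Y,NA
V,NA
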
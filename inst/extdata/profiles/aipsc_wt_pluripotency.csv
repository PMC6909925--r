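concept,expected,provenance
NANOG,up,ESC-signature factor expressed in iPSC
OCT4,up,ESC-signature factor expressed in iPSC
SOX2,up,ESC-signature factor expressed in iPSC
GDF3,up,ESC-signature factor expressed in iPSC
REX1,up,ESC-signature factor expressed in iPSC
FGF4,up,ESC-signature factor expressed in iPSC
DPPA5,up,ESC-signature factor expressed in iPSC
DPPA2,up,ESC-signature factor expressed in iPSC
DPPA4,up,ESC-signature factor expressed in iPSC
hTERT,up,ESC-signature factor expressed in iPSC
SALL4,up,western-blot level comparable between iPSC and hESC
ECAD,up,western-blot level comparable between iPSC and hESC
SSEA34,up,ESC-specific surface antigen
TRA_1_81,up,ESC-specific surface antigen
ALP,up,ESC-specific surface antigen
GAA,up,expressed just above baseline in wild-type cells
MyoD1,down,no sustained endogenous expression in pluripotent state
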
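concept,expected,provenance
lysosomal_glycogen,up,hallmark glycogen accumulation
GAA,down,gene locked off; decreased under glucose deprivation
LAMP2,up,lysosomal marker increased
glucose_deprivation,up,glycogen sequestered away from glycolysis
mTORC1_p,down,mTORC1 activity suppressed with glycogen accumulation
p70S6K_p,down,downstream mTORC1 target phosphorylation suppressed
p4EBP1_p,down,downstream mTORC1 target phosphorylation suppressed
mitochondrial_dysfunction,up,impaired mitochondrial energy metabolism
impaired_energy_metabolism,up,impaired mitochondrial energy metabolism
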
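concept,expected,provenance
NANOG,up,pluripotency retained despite GAA loss
OCT4,up,pluripotency retained despite GAA loss
SOX2,up,pluripotency retained despite GAA loss
SSEA34,up,pluripotency retained despite GAA loss
TRA_1_81,up,pluripotency retained despite GAA loss
lysosomal_glycogen,up,modest accumulation in undifferentiated disease cells
GAA,down,gene locked off in the disease model
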
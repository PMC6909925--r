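concept,expected,provenance
MyoD1,up,mature skeletal muscle marker
CKM,up,mature skeletal muscle marker
MyHC,up,mature skeletal muscle marker
Myogenin,up,mature skeletal muscle marker
Pax7,down,progenitor marker down-regulated on differentiation
NANOG,down,pluripotency lost in differentiated cells
OCT4,down,pluripotency lost in differentiated cells
SSEA34,down,pluripotency lost in differentiated cells
TRA_1_81,down,pluripotency lost in differentiated cells
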
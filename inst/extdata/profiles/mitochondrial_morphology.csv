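concept,expected,provenance
DNM1L,up,mitochondrial shaping protein overexpressed
MFN2,up,mitochondrial shaping protein overexpressed
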
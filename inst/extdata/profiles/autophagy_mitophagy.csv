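concept,expected,provenance
LC3,up,autophagosome marker elevated
p62,up,receptor accumulates with incomplete autophagy
Pink2,up,mitophagy signalling increased
autophagy,up,autophagy active in diseased muscle
mitophagy,up,mitophagy active in diseased muscle
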
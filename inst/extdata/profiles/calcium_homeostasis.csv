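concept,expected,provenance
intracellular_calcium,up,marked increase in intracellular calcium
VDCC,up,increased influx via VDCC-class channels
calpain,up,calcium-activated protease elevated
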
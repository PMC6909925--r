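concept,expected,provenance
ADP,up,markedly elevated under impaired respiration
ATP,down,reduced ATP generation
impaired_energy_metabolism,up,metabolism impaired within the dysfunction subnetwork
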
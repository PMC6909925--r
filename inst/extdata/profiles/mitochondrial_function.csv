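concept,expected,provenance
CytC,up,released from dysfunctional mitochondria
AIF,up,released from dysfunctional mitochondria
ROS,up,reactive oxygen species elevated
Caspase3,up,executioner caspase elevated
apoptosis,up,increased apoptosis
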
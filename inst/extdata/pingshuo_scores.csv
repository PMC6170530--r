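plot,V,S
RUA,0.32,0.25
RP,0.57,0.74
RM,0.16,0.35
PM,0.41,0.46
OP,0.50,0.21
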
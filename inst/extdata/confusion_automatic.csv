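reference,SC,VE,DEJ,PD
SC,1209,58,3,23
VE,71,1085,154,7
DEJ,0,143,1298,160
PD,3,0,143,962
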
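reference,SC,VE,DEJ,PD
SC,1292,1,0,0
VE,23,1285,9,0
DEJ,0,56,1523,22
PD,0,0,26,1082
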
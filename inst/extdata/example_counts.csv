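# n=2000
# excluded=0
type_I2a,type_I2b,count
PD,PD,1613
PD,TT,190
PD,NPD,0
TT,PD,191
TT,TT,5
TT,NPD,0
NPD,PD,1
NPD,TT,0
NPD,NPD,0
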
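tillage,op,WW,WOSR,WB,SB,WFB
CT,plough,1,1,1,1,1
CT,power_harrow,2,2,2,1,0
CT,drill,1,1,1,1,1
RP,plough,1,0,1,1,0
RP,power_harrow,2,0,2,1,0
RP,medium_disc,0,2,0,0,2
RP,drill,1,0,1,1,1
DRT,onepass_cultivator,2,2,2,2,1
DRT,drill,1,0,1,1,1
SRT1,medium_disc,2,2,2,2,2
SRT1,drill,1,0,1,1,1
SRT2,springtine_harrow,2,2,2,2,2
SRT2,drill,1,0,1,1,1
ZT,drill,1,1,1,1,1
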
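crop,grain_2011,grain_2014,straw_2011,straw_2014
WW,172.36,144.56,43.00,43.50
WB,164.42,122.64,59.00,51.92
SB,164.42,122.64,59.00,51.92
WOSR,374.08,290.49,NA,NA
WFB,206.67,221.30,NA,NA
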
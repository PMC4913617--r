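crop,category,sprays,cost_2011,cost_2014,wheat_variant
WW,fungicides,3,68.95,77.93,all
WW,herbicides,3,36.01,44.04,all
WW,growth_regulators,2,22.54,23.50,all
WW,insecticides,1,5.80,4.96,all
WW,seed_treatments_molluscicides,1,14.19,14.81,first
WW,seed_treatments_molluscicides,1,16.09,16.79,other
WB,fungicides,2,45.97,51.95,all
WB,herbicides,2,24.01,29.36,all
WB,growth_regulators,1,11.27,11.75,all
WB,insecticides,1,5.80,4.96,all
WB,seed_treatments_molluscicides,1,13.72,14.32,all
SB,fungicides,2,45.97,51.95,all
SB,herbicides,2,24.01,29.36,all
SB,seed_treatments_molluscicides,1,15.61,16.29,all
WOSR,fungicides,2,29.14,22.13,all
WOSR,herbicides,3,89.43,80.36,all
WOSR,insecticides,2,12.87,11.50,all
WOSR,seed_treatments_molluscicides,2,20.66,24.50,all
WFB,fungicides,2,37.01,30.33,all
WFB,herbicides,2,64.93,73.33,all
WFB,insecticides,2,12.87,13.25,all
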
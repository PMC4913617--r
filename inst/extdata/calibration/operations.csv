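id,implement,power,work_rate_min_ha,kind
plough,plough,tractor_large,70,tillage
power_harrow,power_harrow,tractor_medium,67,tillage
onepass_cultivator,onepass_cultivator,tractor_large,24,tillage
medium_disc,medium_disc,tractor_medium,42,tillage
springtine_harrow,springtine_harrow,tractor_medium,23,tillage
drill,drill,tractor_medium,43,drill
spray,sprayer,tractor_small,8,inseason
fert_spread,spreader,tractor_small,6,inseason
combine,combine,self,35,harvest
swath,swather,self,15,harvest_contract
bale,baler,self,20,harvest_contract
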
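machine,hours,rate
tractor_small,500,0.15
tractor_small,1500,0.27
tractor_medium,500,0.15
tractor_medium,1500,0.27
tractor_large,500,0.15
tractor_large,1500,0.27
combine,150,0.12
combine,450,0.22
swather,150,0.10
swather,450,0.18
baler,150,0.10
baler,450,0.18
plough,100,0.08
plough,600,0.18
power_harrow,100,0.08
power_harrow,600,0.18
onepass_cultivator,100,0.08
onepass_cultivator,600,0.18
medium_disc,100,0.08
medium_disc,600,0.18
springtine_harrow,100,0.08
springtine_harrow,600,0.18
drill,100,0.08
drill,600,0.18
sprayer,100,0.08
sprayer,600,0.18
spreader,100,0.08
spreader,600,0.18
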
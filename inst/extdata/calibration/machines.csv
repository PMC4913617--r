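id,class,weight_kg,price_gbp,lifespan_h,fuel_l_h,spares_rate,insurance_rate,high_use_h
tractor_small,tractor_small,3400,35000,3000,10,0.05,0.0075,1200
tractor_medium,tractor_medium,5600,60000,3000,16,0.05,0.0075,1200
tractor_large,tractor_large,9500,100000,3000,30,0.05,0.0075,1200
combine,combine,14500,180000,3000,30,0.05,0.0075,400
swather,swather,3800,40000,3000,15,0.04,0.0075,400
baler,baler,2600,25000,3000,12,0.04,0.0075,400
plough,implement,1900,15000,3000,NA,0.04,0.0075,600
power_harrow,implement,1850,17000,3000,NA,0.04,0.0075,600
onepass_cultivator,implement,7350,45000,3000,NA,0.04,0.0075,600
medium_disc,implement,1720,14000,3000,NA,0.04,0.0075,600
springtine_harrow,implement,3500,20000,3000,NA,0.04,0.0075,600
drill,implement,3000,35000,3000,NA,0.04,0.0075,600
sprayer,implement,1500,18000,3000,NA,0.04,0.0075,600
spreader,implement,1100,7000,3000,NA,0.04,0.0075,600
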
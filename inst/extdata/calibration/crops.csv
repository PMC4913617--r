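id,species,category,sowing,harvest,grain_yield_t_ha,straw_yield_t_ha,grain_energy_gj_t,straw_energy_gj_t,calorie_kcal_kg,n_rate_kg_ha,p_rate_kg_ha,k_rate_kg_ha,seed_cost_2011,seed_cost_2014,seed_energy_mj_ha,drying_fuel_l_t,fert_passes
WW1,WW,cereal,autumn,late,8.4,3.5,10.0,6.0,3390,190,60,75,55,58,900,12,3
WW2,WW,cereal,autumn,late,6.7,3.0,10.0,6.0,3390,190,60,75,55,58,900,12,3
WWc,WW,cereal,autumn,late,6.2,2.8,10.0,6.0,3390,190,60,75,55,58,900,12,3
WB,WB,cereal,autumn,early,6.9,3.3,8.5,7.0,3520,150,55,70,50,52,850,12,3
SB,SB,cereal,spring,late,5.4,2.7,8.5,7.0,3520,110,45,55,50,52,850,12,2
WOSR,WOSR,break,autumn,early,3.5,0,18.8,0,4940,190,60,40,48,50,60,12,3
WFB,WFB,break,autumn,late,4.0,0,14.7,0,3410,0,50,45,95,100,1200,12,1
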
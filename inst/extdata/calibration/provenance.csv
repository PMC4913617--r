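parameter,tag,note
crops.set,paper,"crop set: first/second/continuous winter wheat, winter and spring barley, winter oilseed rape, winter field beans (published model description)"
crops.grain_yield_t_ha,placeholder,"UK farm-management convention; WW first wheat ~8.4 t/ha, plausible range 7-9"
crops.straw_yield_t_ha,placeholder,"typical cereal straw 2.7-3.5 t/ha"
crops.grain_energy_gj_t,placeholder,"usable energy content; wheat 10 / barley 8.5 GJ/t, rapeseed 18.8 GJ/t (oil-rich), beans 14.7"
crops.straw_energy_gj_t,placeholder,"usable straw energy, 6-7 GJ/t"
crops.calorie_kcal_kg,placeholder,"food-composition convention; 3300-5000 kcal/kg, range reflects oil content"
crops.n_rate_kg_ha,placeholder,"fertiliser recommendation convention; 110-190 kg N/ha, beans zero"
crops.p_rate_kg_ha,placeholder,"fertiliser recommendation convention; 45-60 kg/ha"
crops.k_rate_kg_ha,placeholder,"fertiliser recommendation convention; 40-75 kg/ha"
crops.seed_cost,placeholder,"UK seed cost convention; 48-100 GBP/ha"
crops.seed_energy_mj_ha,placeholder,"seed embedded energy; scales with seed rate"
crops.drying_fuel_l_t,placeholder,"grain drying fuel ~12 L/t"
crops.fert_passes,placeholder,"spreader passes per season"
pesticides.programs,paper,"published pesticide cost table: category costs, spray counts, 2011 and 2014 prices"
machines.weight_kg.onepass_cultivator,paper,"published machinery table: 7350 kg"
machines.weight_kg.medium_disc,paper,"published machinery table: 1720 kg"
machines.weight_kg.springtine_harrow,paper,"published machinery table: 3500 kg"
machines.weight_kg.other,placeholder,"industry-typical machine weights"
machines.lifespan_h,paper,"published machinery table: lifespan assumed 3000 h"
machines.price_gbp,placeholder,"UK list-price convention"
machines.fuel_l_h,placeholder,"10-30 L/h by tractor class, heavy land"
machines.spares_rate,placeholder,"farm-management handbook convention, 4-5% of price per year"
machines.insurance_rate,placeholder,"farm-management handbook convention, 0.75% of price per year"
machines.high_use_h,placeholder,"high annual usage assumption for contractor fee construction"
depreciation.anchors.tractor,paper,"published: straight-line rate 15% at 500 h/yr to 27% at 1500 h/yr"
depreciation.anchors.other,placeholder,"usage-dependent anchors in the same spirit as the tractor anchors"
operations.work_rate.tillage,paper,"published work-rate table: plough 70, power harrow 67, one-pass cultivator 24, medium disc 42, spring-tine 23, drill 43 min/ha"
operations.work_rate.other,placeholder,"spraying, spreading, combining, swathing, baling work-rates"
passes.matrix,paper,"published pass-count matrix by tillage system and crop"
crop_prices,paper,"published crop price table, 2011 and 2014"
contractor_fees,paper,"published contractor fee table, 2011 and 2014"
emission_factors.n2o_ef,paper,"published: 1.6% of applied N released as N2O"
emission_factors.n2o_background_kg_n_ha,paper,"published: background soil emission 1.4 kg N2O-N/ha/yr"
emission_factors.gwp_n2o,placeholder,"100-yr GWP of N2O, 298 (AR4 convention); configurable"
emission_factors.n2o_mass_ratio,paper,"stoichiometric N2O-N to N2O conversion 44/28"
emission_factors.steel_kgco2e_kg,paper,"published machinery table: 1.56 kg CO2-eq per kg steel"
emission_factors.fuel_kgco2e_l,placeholder,"diesel combustion incl. upstream ~3.05 kg CO2-eq/L"
emission_factors.manuf_kgco2e_kg,placeholder,"fertiliser manufacture emissions, N 6.8 / P 1.0 / K 0.6 kg CO2-eq per kg nutrient"
emission_factors.pesticide_kgco2e_spray,placeholder,"pesticide manufacture ~7 kg CO2-eq per spray"
energy_factors.steel_mj_kg,paper,"published machinery table; hourly values fix the working unit at 23 MJ/kg"
energy_factors.fuel_mj_l,placeholder,"diesel energy content 38.7 MJ/L"
energy_factors.manuf_mj_kg,placeholder,"fertiliser manufacture energy, N 45 / P 15 / K 9 MJ per kg nutrient"
energy_factors.pesticide_mj_spray,placeholder,"pesticide manufacture ~120 MJ per spray"
farm.area_ha,paper,"published: 400 ha farm"
farm.interest_rate,paper,"published: interest on capital assumed 3%"
farm.labour_units,placeholder,"two full-time labour units"
farm.machine_units,placeholder,"own fleet: 1 small / 2 medium / 1 large tractor, 1 combine"
periods,placeholder,"work-period structure and hours not published; early autumn / autumn / spring"
n_response,placeholder,"yield response to N level: multipliers 0.82/0.99/1.00 at 50/75/100% of recommended N"
prices.fert.N,paper,"published: 2014 N 750 GBP/t, stated 20% below the 2011 value (937.50)"
prices.fert.P,paper,"published: 2014 P 620 GBP/t, stated 55% above the 2011 value (400)"
prices.fert.K,placeholder,"2011 K base 345 GBP/t placeholder; 2014 stated 2% lower (338.10)"
prices.fuel,placeholder,"red diesel ~0.64 GBP/L in 2011; published statement: unchanged between price years"
prices.wage_2011,placeholder,"farm labour wage ~9 GBP/h in 2011"
prices.wage_2014,paper,"published: 10.19 GBP/h"
prices.contractor_overhead,paper,"published: 25% overhead on machinery cost"
prices.labour_surcharge,paper,"published: 35% surcharge on the labour rate (13.76 GBP/h)"
rotation.transitions,placeholder,"steady-state transition list; published text fixes break-after-cereal and first/second/continuous wheat structure, exact constraint form not printed"
tillage_systems,paper,"published tillage system table: CT, RP, DRT, SRT1, SRT2, ZT; broadcast oilseed rape under RP/DRT/SRT1/SRT2"
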
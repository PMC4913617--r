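farm:
  area_ha: 400.0
  interest_rate: 0.03
  labour_units: 2
  machine_units:
    tractor_small: 1
    tractor_medium: 2
    tractor_large: 1
    combine: 1
periods:
- id: earlyautumn
  unit_hours: 260.0
- id: autumn
  unit_hours: 390.0
- id: spring
  unit_hours: 720.0
emission_factors:
  n2o_ef: 0.016
  n2o_background_kg_n_ha: 1.4
  gwp_n2o: 298.0
  n2o_mass_ratio: 1.571428571428571
  steel_kgco2e_kg: 1.56
  fuel_kgco2e_l: 3.05
  manuf_kgco2e_kg:
    'N': 6.8
    P: 1.0
    K: 0.6
  pesticide_kgco2e_spray: 7.0
energy_factors:
  steel_mj_kg: 23.0
  fuel_mj_l: 38.7
  manuf_mj_kg:
    'N': 45.0
    P: 15.0
    K: 9.0
  pesticide_mj_spray: 120.0
n_response:
- level: 0.5
  multiplier: 0.82
- level: 0.75
  multiplier: 0.99
- level: 1.0
  multiplier: 1.0
prices:
  '2011':
    fert_gbp_kg:
      'N': 0.9375
      P: 0.40
      K: 0.345
    fuel_gbp_l: 0.64
    wage_gbp_h: 9.00
    contractor_overhead: 0.25
    labour_surcharge: 0.35
  '2014':
    fert_gbp_kg:
      'N': 0.75
      P: 0.62
      K: 0.3381
    fuel_gbp_l: 0.64
    wage_gbp_h: 10.19
    contractor_overhead: 0.25
    labour_surcharge: 0.35
tillage_systems:
- id: CT
  wosr_broadcast: false
- id: RP
  wosr_broadcast: true
- id: DRT
  wosr_broadcast: true
- id: SRT1
  wosr_broadcast: true
- id: SRT2
  wosr_broadcast: true
- id: ZT
  wosr_broadcast: false
rotation:
- {from: WOSR, to: WW1}
- {from: WFB, to: WW1}
- {from: WW1, to: WW2}
- {from: WW2, to: WWc}
- {from: WWc, to: WWc}
- {from: WW1, to: WOSR}
- {from: WW2, to: WOSR}
- {from: WWc, to: WOSR}
- {from: WB, to: WOSR}
- {from: SB, to: WOSR}
- {from: WW1, to: WFB}
- {from: WW2, to: WFB}
- {from: WWc, to: WFB}
- {from: WB, to: WFB}
- {from: SB, to: WFB}
- {from: WW1, to: WB}
- {from: WW2, to: WB}
- {from: WWc, to: WB}
- {from: WW1, to: SB}
- {from: WW2, to: SB}
- {from: WWc, to: SB}
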
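# cropmix

Bio-economic optimisation of arable crop mixes under reduced tillage.

## The problem

Reduced and zero tillage promise lower fuel, labour and machinery costs and
smaller greenhouse-gas footprints for combinable-crop farms, but they risk
yield penalties and extra weed-control costs. Whether the trade-off pays
cannot be judged one factor at a time: cultivation speed changes which crops
fit into the autumn work windows, the crop mix changes fertiliser use and
therefore emissions, and machinery ownership costs depend on how much each
machine is actually used. `cropmix` is a whole-farm model for exactly this
question, aimed at agricultural-systems researchers and farm-economics
modellers.

## The model

A 400 ha farm chooses areas `a_k >= 0` of crop *activities* (crop variant
x straw fate x nitrogen level) under one of six tillage systems (CT, RP,
DRT, SRT1, SRT2, ZT). A linear programme

```
max  sum_k gm_k a_k  -  sum_{m,t} fee_m h_{m,t}      (or max NE, min GHG)
s.t. sum_k a_k = 400                                  (land)
     area(c) = inflow(c) = outflow(c)                 (steady-state rotation)
     hours required <= own capacity + hired h_{m,t}   (machine class x period)
     own hours per period <= labour                   (labour)
     area(i) + area(j) <= 0.95 x 400  for all species pairs   (Greening, opt.)
```

chooses the mix; rotation flows only permit agronomic successions (first
wheat after a break crop, barley after wheat, breaks after cereals). The
per-hectare coefficients are built from first principles:

* `gm_k` = revenue − fertiliser − pesticides − seed − fuel (operations +
  grain drying, the only yield-proportional cost) − contractors' fees;
* `ne_k` = output energy − input manufacture energy − fuel energy −
  machinery embedded energy, allocated hourly as `weight x 23 MJ/kg / 3000 h`;
* `ghg_k` = input manufacture + fuel combustion + machinery embedded
  (`weight x 1.56 kg CO2-eq/kg / 3000 h`) + soil N2O, with N2O =
  (1.6% of applied N + 1.4 kg N2O-N/ha/yr) x 44/28 x GWP 298.

A net-margin layer then prices the machinery complement the solution
actually uses (usage-dependent straight-line depreciation, spares, insurance,
3% interest) and own labour; a scenario engine drives tillage comparisons,
yield-penalty breakeven searches (bisection over re-optimised LPs),
black-grass herbicide costs, spring-barley selection sweeps, CAP-Greening
and 2011 vs 2014 price years.

The shipped calibration combines every published parameter (pass counts and
work-rates, implement weights and steel factors, pesticide and crop price
tables, contractor fees, emission factors) with clearly-tagged placeholder
values for the predecessor calibration that was never published; see the
provenance sidecar (`inst/extdata/calibration/provenance.csv`) and the
methods vignette (`vignettes/cropmix-methods.Rmd`).

## Worked example

```r
library(cropmix)
b <- paperlike_calibration()

sol <- optimize_farm(b, "ZT", "2011", "max_GM")
print(sol)
#> <farm_solution> ZT / max_GM / 2011
#>   WW1:SR:N75       200.00 ha
#>   WOSR:none:N75    200.00 ha
#>   GM        387809 GBP/farm
#>   NE       28122.5 GJ/farm
#>   GHG      1291536 kg CO2-eq/farm
#>   fuel       47678 L/farm, contractor fees 5892 GBP

net_margin(sol, size_complement(sol, b), b)
#> <net_margin_report> ZT / 2011
#>   GM              387809 GBP/farm (970 /ha)
#>   fuel             47678 L (30514 GBP)
#>   contractors       5892 GBP
#>   machinery        86018 GBP (215 /ha)
#>   labour           10320 GBP (26 /ha)
#>   NM              291471 GBP/farm (729 /ha)

yield_threshold(b, "ZT", "GM")
#> <threshold_result> ZT / GM
#>   p* = 0.0935 (baseline 3.357e+05, value at p* 3.357e+05)
```

Read: under zero tillage the profit-maximising farm drills 200 ha of first
wheat (straw baled, 75% of recommended N) and 200 ha of oilseed rape,
earning a GBP 387,809 gross margin — against GBP 335,682 for the ploughed
system, whose slow cultivation forces a third of the farm into winter
barley and GBP 27k of contracting. Owning no plough, power harrow or large
tractor, the zero-tillage farm nets GBP 729/ha. The breakeven search says
its yields could fall 9.35% across all crops before its gross margin drops
to the conventional baseline. (All absolute figures are properties of the
shipped calibration; the placeholder parameters are documented, and the
tests assert orderings and identities, not these numbers.)

A thin command-line driver over the same functions is installed at
`inst/cli/cropmix.R`:

```sh
Rscript inst/cli/cropmix.R optimize --tillage ZT --objective gm --prices 2011 --out out/
Rscript inst/cli/cropmix.R sweep-yield --tillage ZT --metric gm
```

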
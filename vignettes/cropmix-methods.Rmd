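---
title: "The cropmix bio-economic farm model: methods and assumptions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The cropmix bio-economic farm model: methods and assumptions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cropmix)
```

## The model

`cropmix` is a single-year, steady-state bio-economic model of a 400 ha UK
combinable-crop farm. The farm chooses a crop mix from winter wheat (first,
second and continuous wheats, `WW1`/`WW2`/`WWc`), winter and spring barley
(`WB`, `SB`), winter oilseed rape (`WOSR`) and winter field beans (`WFB`),
each grown under one of six tillage systems of decreasing intensity:

* `CT` — conventional: plough plus two power-harrow passes, then drill;
* `RP` — rotational ploughing: conventional before cereals, two disc-harrow
  passes before break crops;
* `DRT` — deep reduced tillage: two passes of a heavy one-pass cultivator
  (one for beans), large tractor;
* `SRT1`, `SRT2` — shallow reduced tillage: two passes of a medium disc or a
  spring-tine harrow;
* `ZT` — zero tillage: the seed drill alone.

Under `RP`, `DRT`, `SRT1` and `SRT2` the oilseed rape seed is broadcast
together with the tillage passes, so no separate drill pass (time, fuel or
embedded burden) is incurred; under `CT` and `ZT` it is drilled.

An *activity* is a crop variant x straw fate (baled and sold, `SR`, or
incorporated) x nitrogen level (50, 75 or 100% of the recommended rate).
Three whole-farm metrics are computed for each activity, per hectare:

* **Gross margin (GM, GBP/ha)** — grain revenue, plus straw revenue where
  baled, less fertiliser, pesticide programme, seed, fuel for all field
  operations and grain drying, and contractors' fees. Grain drying fuel is
  the only yield-proportional cost; everything else is fixed per hectare,
  which is why optimised GM is piecewise-linear in a uniform yield penalty.
* **Net energy (NE, MJ/ha)** — usable energy in outputs minus the
  manufacture energy of fertiliser, pesticides and seed, fuel energy, and
  machinery embedded energy allocated by hours of use
  (`weight x 23 MJ/kg / 3000 h`).
* **GHG (kg CO2-eq/ha)** — input manufacture, fuel combustion, machinery
  embedded emissions (`weight x 1.56 kg CO2-eq/kg / 3000 h`) and soil
  nitrous oxide: 1.6% of applied N plus a background 1.4 kg N2O-N/ha/yr,
  converted by 44/28 and a GWP of 298 (configurable; 298 is the AR4 100-yr
  convention of the period).

The published hourly emission rates for the three reduced-tillage implements
(3.83, 0.90, 1.81 kg CO2-eq/h) are not mutually consistent with
`weight x 1.56 / 3000` under any single rounding; `cropmix` always computes
from the formula (giving 3.82, 0.89, 1.82). Similarly the steel energy
factor is printed with a GJ/kg unit, but the printed hourly values (e.g.
7350 kg -> 56.35 MJ/h) fix the working unit at 23 MJ/kg, which is what the
package uses.

## The farm linear programme

Decision variables: activity areas (ha), steady-state rotation flows
(ha moving from predecessor crop to successor crop each year) and contracted
hours per machine class and work period. Constraints:

* land: areas sum to 400 ha;
* rotation: each crop's area equals both its inflow and outflow of
  transition variables. Permitted transitions: break -> first wheat; first
  wheat -> second wheat -> continuous wheat -> continuous wheat; any cereal
  -> break; wheat -> barley. Barley after barley is excluded: with it, the
  optimiser could hold the whole farm in barley, which the rotation
  constraints exist to prevent (they keep mixes "agronomically
  appropriate"); barley occupies the second-cereal slot after wheat.
* resources: three work periods (early autumn, autumn, spring). Each
  (machine class, period) has own-fleet capacity; labour caps the summed
  own hours per period. Contracted hours relax both at the per-class fee
  and are bounded by the hours actually required. Establishment hours load
  the period implied by the transition: spring crops in spring, oilseed
  rape always in the narrow early-autumn window, otherwise early autumn
  after early-harvested predecessors (winter barley, oilseed rape) and
  autumn after late ones (wheat, beans). This timing rule is what makes
  winter barley valuable under conventional tillage — it spreads the
  workload — and lets the faster reduced-tillage systems drop it.
* Greening (optional): every pair of species is capped at 95% of the land
  (380 ha), which with full land use simultaneously enforces at least three
  species, the linear equivalent of the "two main crops <= 95%" rule.

Objectives: maximise GM (contracted hours priced at fees), maximise NE or
minimise GHG (both pure coefficient sums; machinery burdens are allocated
by hours of use whoever owns the machine, so contracting does not change
them). A tiny index-proportional perturbation (1e-7 GBP/ha per activity
index) makes the chosen vertex deterministic among alternate optima,
preferring low activity indices. The LP is solved with a two-phase simplex
(`boot::simplex`); the rotation-balance equalities are reduced to a
full-rank subset first (total inflow always equals total outflow, so one
row is redundant and would otherwise break phase 1). Solutions report all
three metrics recomputed from areas x coefficients, and the own/contracted
split is post-processed with a deterministic minimal-hire rule (own
capacity first; when labour binds, the cheapest class is hired first).

## Net margin

Net margin = GM less machinery ownership costs and own labour (fuel and
contractor fees are already inside GM). The farm owns exactly the machines
whose operations appear with positive own-farm hours; swathing and baling
are always contracted. Per machine and year: straight-line depreciation at
a usage-dependent rate, piecewise-linear between anchor points (tractors:
15% at 500 h/yr to 27% at 1500 h/yr, clamped outside) times purchase
price; spares & repairs and insurance as flat price fractions; interest at
3% of half the purchase price (average invested capital — the base is a
package choice, only the 3% rate is fixed by the model description).
2014 contractor fees can be constructed from machine costs at high usage
with a 25% overhead plus labour at a 35% surcharge (10.19 x 1.35 = 13.76
GBP/h); 2011 fees are read directly from the fee table.

## Scenario engine

* **Yield-penalty thresholds**: bisection on the uniform penalty `p`,
  re-optimising the LP at each step, until the system's metric equals the
  conventional-tillage baseline at `p = 0`. Metrics: GM, NE, GHG per tonne
  of output, and total GHG at constant production (farm GHG plus the GHG of
  the extra hectares needed to restore baseline calorie output). The
  bisection interval is shrunk below 5e-5 so the result is comparable to a
  0.1%-step grid scan within 0.001. A total-penalty farm has zero output;
  its per-output metrics are treated as +Inf when bracketing.
* **Land compensation**: extra land fraction = baseline output / penalised
  output − 1, computed for tonnes (grain plus baled straw) and calories
  (grain only); the calorie basis is used for the extra-land GHG because
  the constant-production comparison is about food energy supplied.
* **Weed control**: a black-grass herbicide applied every other year at
  85 GBP/ha is annualised to 42.50 GBP/ha/yr on every activity (the extreme
  variant charges the full 85); the extra spraying pass adds 4.81 GBP/ha to
  net-margin costs. Whether that spraying charge follows the application
  frequency or is annual is not fixed by the model description; the default
  follows the application frequency (`spray_basis = "per_application"`),
  with a switch. The pass's field time is not added to the period balances;
  at one sprayer pass per year the effect on resource use is negligible
  against its cost, which is carried in full.
* **Spring-barley sweep**: a penalty applied to every crop except spring
  barley, reporting its optimised area, entry threshold and the penalty at
  which it exceeds 100 ha.
* **Scenario matrix**: every (price year, tillage, objective, Greening)
  combination, with pairwise deltas against conventional tillage reported
  in the model's own style — nearest integer percent and nearest GBP/ha.

## The shipped calibration and what it does (and does not) show

The package ships one default calibration (`paperlike_calibration()`).
Parameters are tagged in a provenance sidecar as `paper` (published values:
the tillage systems, pass matrix and work-rates, the three implement
weights and steel factors, pesticide programmes and both price years,
contractor fee tables, fertiliser price statements, emission factors, farm
area, interest rate, wage and fee-construction markups, tractor
depreciation anchors) or `placeholder` (the calibration inherited from the
model's predecessor and not published: yields, nitrogen response, energy
and calorie contents, fuel-use rates, input manufacture factors, machinery
prices, work periods and labour). Placeholder magnitudes were anchored to
UK farm-management conventions and fixed once so that the model's
qualitative behaviour matches the published account:

* conventional tillage selects the three-way wheat / winter barley /
  oilseed rape mix (133.33 ha each) under maximised GM, with contractors
  hired for cultivation;
* GM and NM rise and fuel falls monotonically from CT through RP and the
  reduced systems to ZT; minimised GHG is lower under ZT than CT;
* maximised NE selects first wheat with beans under CT but first wheat
  with (broadcast) oilseed rape under the reduced systems — a deliberate
  knife-edge: rapeseed's usable energy (18.8 GJ/t) is set so the drill
  pass saved by broadcasting flips the break-crop choice;
* minimised GHG selects half low-nitrogen wheat, half beans; under
  Greening a 20 ha slice of spring barley (low N) enters;
* the nitrogen response (multipliers 0.82 / 0.99 / 1.00 at 50 / 75 / 100%
  N) is steep below 75% and nearly flat above, so profit and energy
  optima sit at 75% N while the emission optimum drops to 50%.

Because the inherited calibration is emulated, the model's *absolute*
numbers (GMs around 336-390 kGBP/farm, NE around 27-28 GJ x 10^3/farm,
thresholds of 9.4% for GM and 3.0% for NE on this fixture) are properties
of the shipped placeholders, not reproductions of the published absolute
values; only the orderings, structures and identities above are asserted
by the test suite. One honest divergence: on this fixture the
GHG-per-tonne threshold does not exist (the profit-optimal zero-tillage
mix is so rape-heavy that its emissions per tonne start above the
conventional baseline), and `yield_threshold()` reports `"no threshold"`
rather than a number.

`random_calibration(seed)` perturbs the default with documented uniform
ranges (yields and prices +/-10%, work-rates +/-15%, fuel rates +/-10%,
period hours +/-20%) for property tests; prices and physics are drawn
independently, so a price draw never changes hours, fuel, NE or GHG.

## Numerical choices

* Land balance tolerance 1e-6 ha; areas clipped at zero below 1e-9.
* Simplex pivot tolerance 1e-9, iteration cap 50x the variable count.
* Monetary values are GBP with two-decimal reporting; energy is MJ
  internally and GJ in reports.
* Degenerate inputs: a zero-weight machine has zero embedded burden; a
  zero-cost machine's constructed contractor fee is the surcharged labour
  alone; an all-zero yield multiplier is a valid GM problem but has no
  defined land compensation (an error says so).
* Problem sizes: the full farm programme has 34 activities, 21 rotation
  flows and 12 contracting variables; a solve takes well under a second,
  and the brute-force oracle tests run on a 60 ha farm so the 1 ha grid
  over three crops stays small.

## Known limitations

No within-season dynamics, stochastic yields, pest-population or soil
carbon model; no tillage-nitrogen interaction (held constant across
systems, as in the published model); no tax, subsidy (decoupled), finance
or second-hand machinery market; work-period structure is a three-period
simplification of the farm year.
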
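# soccost

Marginal cost curves for soil organic carbon (SOC) sequestration from
no-till adoption on cropland.

## What it does, and for whom

Cropland soils lose carbon under intensive tillage and can regain part
of it when soil disturbance is reduced. `soccost` is for
agro-environmental economists and inventory analysts who want to know
not only *how much* SOC a no-till (NT) conversion scenario could store,
but *at what cost per tonne of CO₂*. It chains three standard pieces
into one reproducible pipeline:

1. **Biophysical accounting (IPCC Tier 1).** The equilibrium SOC stock
   of a land unit is the product

   *SOC = SOC_ref(climate, soil) · F_LU · F_MG · F_I*

   where *SOC_ref* is the 0–30 cm reference stock under native
   vegetation and *F_LU*, *F_MG*, *F_I* are the climate-dependent
   land-use, management (tillage) and input multipliers. A management
   change moves the stock linearly to the new equilibrium over
   *D* = 20 years, so the annual rate of a tillage change is
   *(SOC_to − SOC_from)/D* in Mg C ha⁻¹ yr⁻¹ (× 44/12 for the CO₂
   basis). Each stratum's tillage history across three inventory dates
   (1982, 1997, 2017) is classified into one of nine transition
   sequences (`CTCTNT`, `CTRTNT`, …, `NCNTNT`); land already under NT
   at the middle date sequesters nothing more, and land out of crops
   (set-aside/CRP, hay, pasture) is excluded as non-convertible.

2. **Pricing.** Each convertible stratum is priced with its state's
   conservation-program payment for NT adoption:

   *C_value = payment ($ ha⁻¹ yr⁻¹) / rate (Mg CO₂ ha⁻¹ yr⁻¹)*,

   giving $ Mg⁻¹ CO₂. An optional reserve-pool fraction withholds part
   of the credited rate as insurance against reversal.

3. **Curve assembly.** Sorting strata by unit cost with cumulative
   annual quantity yields the marginal cost (supply) curve of
   sequestration, queryable for the quantity available below any price
   and summarised against benchmark thresholds such as the
   geologic-storage cost range ($36.36–$86.06 Mg⁻¹ CO₂ in 2014
   dollars).

A seeded synthetic generator (`generate_bundle()`) emulates the
survey-strata structure of the real inputs, so the entire pipeline is
testable and demonstrable without restricted micro-data.

## Worked example

Using the small bundled example inputs (twelve strata across four
climate zones, with the default Tier-1 factor tables):

```r
library(soccost)
ft  <- load_factor_table(soccost_example("factors.csv"))
rt  <- load_ref_stocks(soccost_example("ref_stocks.csv"))
inv <- soc_inventory(soccost_example("example_strata.csv"), ft, rt)
summary(inv)
```

```
Sequence  Area (Mha)  Area (%)  Annual C (CO2) (Tg/yr)  20-yr C (CO2) (Tg)  C (%)  Rate C (CO2) (Mg/ha/yr)
CTCTNT    2.0         47.2      0.7 (2.6)               14 (52)             70.5   0.35 (1.3)
CTRTNT    0.8         18.9      0.1 (0.5)               3 (9)               12.9   0.16 (0.6)
CTNTNT    0.3         7.1       0.0 (0.0)               0 (0)               0.0    0.00 (0.0)
RTCTNT    0.1         2.1       0.0 (0.1)               0 (1)               1.8    0.20 (0.7)
RTRTNT    0.4         9.9       0.0 (0.1)               1 (2)               3.2    0.08 (0.3)
RTNTNT    0.2         5.2       0.0 (0.0)               0 (0)               0.0    0.00 (0.0)
NCCTNT    0.2         3.5       0.1 (0.2)               1 (4)               6.1    0.41 (1.5)
NCRTNT    0.3         6.1       0.1 (0.2)               1 (4)               5.5    0.21 (0.8)
Total     4.2         100.0     1.0 (3.7)               20 (73)             100.0  0.24 (0.9)
```

Each row is one tillage-transition sequence: its convertible area, the
annual carbon it would store after NT conversion (C with the CO₂
companion in parentheses), the 20-year totals, and the area-weighted
mean sequestration rate. The `…NTNT` rows are land already under
no-till in 1997 — zero additional storage, reported but never priced.

Pricing the inventory with the example payment schedule and querying
the curve:

```r
mc <- build_curve(inv, load_payments(soccost_example("example_payments.csv")))
mc
predict(mc, c(36.36, 86.06))
```

```
Marginal cost curve for SOC sequestration via no-till adoption
  points: 8 strata, 4 excluded
  unit cost range: $14.15 to $419.03 per Mg CO2
  annual quantity on curve: 3.7 Tg CO2/yr (potential 3.7)

[1] 2.766014 3.034617
```

So of the 3.7 Tg CO₂ yr⁻¹ total potential, 2.77 Tg yr⁻¹ is available
at unit costs strictly below the low geologic-storage benchmark and
3.03 Tg yr⁻¹ below the high one. `summary(mc)` breaks those quantities
down by sequence with within-threshold and share-of-potential
percentages, and `plot(mc)` draws the supply step function.
`run_pipeline()` wraps the whole chain and writes the unrounded CSVs
plus fixed-precision rendered tables;
`inst/scripts/soccost-report.R` exposes the same pipeline on the shell.

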
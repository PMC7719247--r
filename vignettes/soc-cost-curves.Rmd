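---
title: "Costing soil carbon sequestration from no-till adoption"
author: "soccost"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Costing soil carbon sequestration from no-till adoption}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soccost)
```

## The model

`soccost` couples a Tier-1 soil carbon inventory to a payment-based
pricing rule and assembles the result into a marginal cost curve. This
vignette explains the model, its assumptions, the tunable parameters,
and the design decisions taken where the method left genuine choices.

### Tier-1 SOC accounting

The equilibrium soil organic carbon stock of a land unit (0–30 cm) is

$$\mathrm{SOC} = \mathrm{SOC}_{ref}(c, s)\; F_{LU}(u, c)\; F_{MG}(t, c)\; F_{I}(i, c)$$

with climate zone $c$, soil class $s$, land use $u$, tillage $t$ and
input level $i$. All five dimensions are closed enumerations
(`climate_zones()` and friends); factor values are configuration
shipped as editable CSV defaults (`soccost_example("factors.csv")`),
not code, and no default value is treated as an oracle by the test
suite. The method assumes the stock approaches its new equilibrium
linearly over $D$ years, so a management change sequesters
$(\mathrm{SOC}_{to} - \mathrm{SOC}_{from})/D$ annually for $D$ years
and nothing thereafter.

Strata carry their management at three inventory dates — 1982, 1997
and a 2017 scenario date — and are classified into nine transition
sequences (first element CT, RT or NC for non-crop; middle element
CT/RT/NT; final element always NT because the scenario converts every
convertible hectare to no-till at the 1997 inventory). Two exclusion
rules follow the scenario definition: land out of crop production in
1997 (set-aside/CRP, hay, pasture) cannot be converted and is flagged
ineligible; land already under NT in 1997 undergoes no further
management change and contributes exactly zero.

**Chaining assumption.** The package assumes each inventory's end
state has fully equilibrated by the next inventory date, so the final
period's rate depends only on the 1997 state and that same state with
tillage replaced by NT. The 1982 state influences results only through
sequence labelling and composition. The first inventory interval is 15
years while $D = 20$; full equilibration by 1997 is recorded here as a
modelling assumption, chosen because it makes the `…NTNT` sequences
exactly zero and lets weighted-average differences between, say,
`CTCTNT` and `NCCTNT` arise purely from composition — both properties
the aggregate tables display.

Units are chosen so aggregation is exact: rates in Mg C ha⁻¹ yr⁻¹,
areas in ha, 1 Tg = 10⁶ Mg, hence Tg yr⁻¹ = (Mg ha⁻¹ yr⁻¹) × (Mha)
numerically. The C→CO₂ conversion is stored as the exact rational
44/12; the decimal 3.67 never enters a computation, and rounding
happens only in the reporting layer.

### Pricing and the cost curve

Each convertible stratum is priced by the payment rule

$$C_{value} = \frac{\text{payment } (\$\,\mathrm{ha}^{-1}\,\mathrm{yr}^{-1})}
                   {\text{rate } (\mathrm{Mg\,CO_2\,ha^{-1}\,yr^{-1}})}$$

using its state's conservation-program payment (payments vary across
states but not within one; program rules on payment duration and
maintenance are documented but deliberately not modelled — the payment
is used purely as the observed cost of switching to NT). Strata with
zero or negative rates have no defined cost: they raise a classed
`undefined cost` condition if priced directly, and the curve builder
routes them to a first-class exclusion table with reasons instead of
pricing them at infinity.

The curve sorts points by unit cost, breaking ties lexicographically
by stratum id so equal-cost output is bit-identical across runs.
`quantity_below()` uses a **strict** "<" comparison at thresholds,
matching the "for less than" phrasing of threshold reporting;
threshold boundary behaviour is therefore explicit and testable.
Shares are computed from unrounded internals and rounded only when
rendered.

## Tunable parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `horizon` (D) | 20 | yr | time to SOC equilibrium; also the crediting horizon |
| CO₂/C ratio | 44/12 | – | exact rational; overridable nowhere |
| `deflator` | 36.36/30 | – | carries 2005 dollars to 2014 dollars ($30→$36.36, $71→$86.05); any positive factor accepted. The companion high bound is often quoted as $86.06 from an unrounded index; this package reports its own product, 86.052 |
| `thresholds` | 36.36, 86.06, 100 | $ Mg⁻¹ CO₂ | geologic-storage cost range plus a round benchmark |
| `reserve_fraction` | 0 | – | fraction of the rate withheld in a reserve pool (e.g. 0.20); multiplies every unit cost by 1/(1−f) |
| factor uncertainty | LU 12, MG 10, I 15 | % | reported relative uncertainties, used only by `sensitivity_sweep()` |

## The synthetic generator

Real inputs at the needed resolution (survey micro-data, tillage
adoption tables, per-state payment schedules) are not publicly
distributable, so `generate_bundle()` draws a statistically analogous
bundle, fully determined by one master seed through a fixed stream
order (sequences, areas, climate, soil, rotation, state, region,
factor tables, reference stocks, payments).

Default study conditions:

* nine-sequence area shares of 57.9, 23.2, 2.2, 0.1, 0.9, 4.8, 6.9,
  3.1, 0.9 percent. The second-largest intensification sequence
  `RTCTNT` is a trace category in the national inventory (0.1 Mha);
  we give it 0.1 % so all nine codes occur while shares still sum to
  exactly 100, which takes 0.1 from the leading `CTCTNT` share;
* a 124.7 Mha national total. Stratum areas are lognormal
  (`area_sdlog = 1`, a realistic heavy tail for survey expansion
  weights) rescaled so the generated total is exact;
* convertible rates constrained to 0.12–0.47 Mg C ha⁻¹ yr⁻¹, the
  span of regional weighted averages for U.S. cropland. The generator
  enforces this *indirectly*: it draws tillage-factor deltas and
  land-use factors per climate zone, then solves for the feasible
  reference-stock band per (climate, soil) such that every
  input-level/transition combination lands inside the bounds, and
  errors if the configured range is infeasible. Rates are never
  written into strata, so the real Tier-1 pipeline is genuinely
  exercised by every synthetic run;
* 48 states with payments uniform on $18.29–$125.73 ha⁻¹ yr⁻¹.

`expected_aggregates()` returns the configured shares with
3-standard-error tolerances. For a share $p$ with independent
heavy-tailed areas the area-share standard error is
$\sqrt{p(1-p)(1+cv^2)/n}$, $cv$ the area coefficient of variation, so
tolerances scale as $1/\sqrt{n}$.

**What the generator does not emulate:** geographic structure (no
county geometry or climate surfaces; region labels are uniform), the
real joint distribution of sequence × climate × rotation (drawn
independently unless a cross-table is supplied), and the correlation
between payments and climate. Passing recovery tests therefore shows
the pipeline is self-consistent under the stated marginal conditions,
not that it reproduces the national absolute totals, which depend on
the unavailable joint micro-data.

## Numerical choices

* **Rounding.** Half-away-from-zero at the reporting layer only
  (`round_half_away()`): rates and percentages to one decimal (the
  C-basis weighted rate to two), currency to two, 20-year totals to
  integers. Unrounded CSVs are always emitted beside rendered tables.
* **Ties and determinism.** Curve ties break by stratum id; the
  generator and the sensitivity sweep save and restore the caller's
  RNG state; reruns of `run_pipeline()` are byte-identical (the run
  log records input digests, not timestamps).
* **Degenerate inputs.** Empty strata tables, empty curves, zero
  total potential, non-positive horizons and reserve fractions outside
  $[0,1)$ all raise classed errors rather than returning empty
  reports.
* **Sensitivity sweep.** Reported factor uncertainties are treated as
  95 % half-widths of a multiplicative normal error
  (sd = pct/100/1.96), truncated away from zero; perturbation happens
  at the factor level (not on rates) and each draw re-runs the full
  inventory and curve.

## Problem sizes

The test suite exercises the pipeline at sizes chosen to make sampling
arguments valid while keeping the default run quick: 5 000 strata for
parameter recovery (3-SE tolerances), 1 000 random curves of up to 100
points against a brute-force quantity oracle, and tens-to-hundreds of
strata elsewhere. The full suite runs in well under a minute.

## Known limitations

* Tier 1 only: no measurement- or model-based (Tier 2/3) estimation,
  a single 0–30 cm pool, no N₂O/CH₄ accounting, no depth profiles.
* Instantaneous conversion at the 1997 inventory; no adoption
  dynamics, no discounting over the 20-year horizon, no
  transaction/monitoring costs, and no enterprise-budget profit
  comparison — the payment is the entire cost signal.
* Negative rates (tillage intensification constructed outside the
  conversion scenario) are computed and flagged but excluded from
  curves.
* The printed-precision renderer reproduces conventional table
  layouts; it is intentionally not a general-purpose formatter.
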
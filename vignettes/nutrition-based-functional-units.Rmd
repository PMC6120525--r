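---
title: "Nutrition-based functional units for livestock carbon footprints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nutrition-based functional units for livestock carbon footprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutrifu)
```

## The problem

Comparative LCA of livestock systems conventionally divides greenhouse-gas
burdens by a mass of product. A kilogram of forage-finished beef, however,
is not nutritionally interchangeable with a kilogram of concentrate-finished
beef or broiler meat: feeding strategy changes omega-3 content several-fold,
and species differ widely in micronutrients such as vitamin B12, selenium
and zinc. `nutrifu` re-expresses emission intensities under functional
units that carry nutritional meaning — a gram of a nutrient, or one percent
of a day's recommended intake — so that systems are compared on what they
deliver to human nutrition rather than on tonnage.

## The conversion chain

Emission intensities arrive on heterogeneous mass bases (per kg liveweight,
carcass weight or edible meat, depending on the source study). The chain is

- liveweight → carcass: multiply the mass by the kill-out fraction
  $k \in (0,1]$;
- carcass → edible meat: multiply by the meat yield $m \in (0,1]$
  (1 minus the bone/fat/drip wastage rate).

Because the animal's total burden is fixed, the *intensity* moves in the
opposite direction to the mass:
$\mathrm{GWP}_{meat} = \mathrm{GWP}_{LW} / (k\,m)$. `mass_fraction()`
returns the kg of target mass per kg of source mass (reciprocal when moving
up the chain, 1 for identical bases) and `rebase_emissions()` divides by
it. Rebasing toward the larger mass is allowed — the analysis only ever
moves toward meat, but the inverse direction makes round-trip testing
possible, and the suite checks liveweight → meat → liveweight recovery to
$10^{-12}$ relative.

Coefficients are consumed strictly as fractions; loaders convert
percent-style inputs at the boundary so a silent factor-100 error cannot
enter the arithmetic. Zero coefficients are rejected at construction, which
is where a division by zero mass would otherwise originate.

## Nutrient-mass functional units

For a nutrient present at $c$ mg per 100 g meat, one kg of meat carries
$c/100$ g of it, so

$$\mathrm{GWP}_{nutrient} = \frac{\mathrm{GWP}_{meat}}{c/100}
\quad [\text{kg CO}_2\text{-eq per g}].$$

Total omega-3 and the EPA+DHA subgroup (the most bioactive long-chain
omega-3 fatty acids) are the motivating cases, but any stored nutrient can
serve: the fatty-acid summary of each system is mirrored into the nutrient
namespace at construction, so one mechanism covers all functional units.
A genuine zero content (chicken meat contains no vitamin B12) makes the
unit undefined for that system; `evaluate_systems()` excludes such systems
from the ranking with a warning instead of propagating an infinite burden.

## The UKNI index engine

A nutrient index collapses a composition into one scalar. The four UKNI
specifications score 100 g of product as the mean percent-of-reference
over qualifying nutrients minus, for the "-2" variants, the mean
percent-of-reference over the limit nutrients SFA and sodium:

$$\mathrm{UKNI} = \frac{1}{|Q|}\sum_{i\in Q}\frac{100\,c_i}{RDI_i}
 \;-\; \frac{1}{|D|}\sum_{j\in D}\frac{100\,c_j}{RDI_j}.$$

Two numerical conventions matter and both are deliberate:

- **No capping.** Individual terms may exceed 100 % (100 g of beef covers
  133 % of the vitamin B12 reference). The published 10-nutrient beef
  scores are only reproduced without a cap, and capping would discard
  exactly the information that makes beef rank well under these indices.
- **Limit nutrients are ordinary ratios.** Sodium (6 g/day) and SFA
  (25 g/day) enter the same percent computation; their `limited` role only
  routes them to the penalty term.

The functional form itself (mean-of-percents minus mean-of-percents) was
chosen because it reproduces every unpenalised published index cell to the
printed digit and all penalised cells within 0.1; pooled-denominator and
capped alternatives miss by more than 1. Reference intakes are UK
female/male averages, with MUFA and EPA+DHA references adopted from the
Finnish protein-food index family where no UK recommendation exists; no
sex-specific tables are in scope.

The burden per index point divides the GWP of 100 g of meat by the % RDI
that those 100 g deliver:
$\mathrm{GWP}_{index} = (\mathrm{GWP}_{meat}/10)/\mathrm{UKNI}$, in kg
CO2-eq per 1 % of a day's recommended intake.

## Tunable parameters

| Parameter | Unit | Default | Why |
|---|---|---|---|
| kill-out fraction | kg carcass / kg liveweight | per system (0.474 for lamb) | slaughter yield of the species/system |
| meat yield | kg meat / kg carcass | per system (0.87 beef, 0.88 lamb, 0.54 pork) | bone/fat/drip wastage complement |
| reference intakes | per day | packaged UK table | denominator of every percent term |
| index specification | nutrient lists | four UKNI variants | which nutrients are rewarded/penalised |
| display rounding | decimals | 1 | matches the study tables; never feeds back into computation |

All internal arithmetic is double precision end to end; rounding exists
only in the display CSVs written by `cmd_score()`/`cmd_footprint()`, with
full-precision JSON alongside.

## Known inconsistencies in the source tables

The packaged inputs reproduce the published results from their own inputs,
which exposes three small internal inconsistencies of the source analysis;
the package documents them rather than patching them:

- The published mass-based intensity for concentrate beef (9.8) does not
  follow from its own inputs: 7.9 kg CO2-eq/kg carcass at 0.87 kg meat/kg
  carcass gives 9.08. The chain is not special-cased; `load_published_gwp()`
  exposes the published rounded column for analyses (such as the
  per-index-point rankings) that take it as input, which is exactly how the
  published per-index-point comparison was computed.
- Prose wastage rates (13.0 % beef, 12.2 % lamb) and the tabulated meat
  yields (0.87, 0.88) are not mutually exact; the fixtures follow the
  tabulated values, which reproduce the published footprints within printed
  rounding.
- A few quality-based cells (e.g. lamb EPA+DHA 99.2 vs 98.98 unrounded)
  reflect rounding of intermediates in the original spreadsheet.
  Comparisons in the test suite use tolerances (±0.15 on footprints, ±0.1
  on index scores) instead of emulating that rounding.

## The synthetic-study generator

`generate_study()` produces structurally valid random systems so every
pipeline stage is property-testable without the fixtures: GWP uniform on
[1, 40] kg CO2-eq/kg, kill-out on [0.4, 0.8], meat yield on [0.5, 0.95],
total omega-3 on [10, 500] mg/100 g with EPA+DHA drawn as a [0.05, 0.5]
fraction of it (so the subgroup constraint holds by construction), the
emissions basis uniform over the three bases, and each composition nutrient
uniform on its span across the seven study systems widened by 50 % and
clipped at zero — chosen so synthetic index scores land in the realistic
5–35 % RDI band. Each system draws from a private stream keyed by
`(seed, index)`, so adding or removing systems never perturbs the others,
and generation is reproducible across processes.

What the generator does *not* emulate: biological covariance between
nutrients (SFA and MUFA rise together in real meat; draws here are
independent), species-typical composition differences, and measurement
error structure. Passing property tests on synthetic studies therefore
demonstrates the arithmetic and its invariants (monotonicity, scale
invariance, rank invariance under common GWP rescaling), not the realism
of any particular synthetic system.

## Design choices made where the design was open

- **Identity coefficients for chicken** (GWP already per kg meat) keep the
  chain uniform instead of branching per species; for beef and pork, whose
  GWP basis is carcass, the kill-out slot holds a placeholder 1.0 that the
  chain never exercises.
- **Nutrient names are canonicalised** case-insensitively with a fixed
  alias list ("EPA+DHA" ≡ "DHA+EPA", "Vitamin B12" ≡ "B12"), so fixtures
  and user configuration files interoperate; unknown names pass through
  normalised, keeping the engine open to arbitrary nutrients.
- **Ties in rankings** share the lower rank and order deterministically by
  system label, so outputs are diffable.
- **Omega-3 reference for synthetic studies**: when a synthetic profile
  carries total omega-3 as a scored nutrient, the generator's reference
  table uses the UK long-chain omega-3 guideline of 450 mg/day; the study
  indices themselves only ever score EPA+DHA, for bioavailability.

## Problem sizes

The suite runs the seven study systems throughout, 1000-case random sweeps
for the oracle-equivalence and generator-validity properties, and
20-system synthetic studies for the monotonicity/scale suites; the full
test run takes a few seconds on one CPU.

## Limitations

Everything upstream of the per-kg GWP figure is out of scope: no farm
inventory modelling, feed rations or emission factors — GWP per reference
mass is an input. Cooking losses are excluded to match the (uncooked)
composition data. There is no per-cut yield modelling beyond the single
meat-per-carcass fraction, no per-kcal or per-serving index bases, no
bioavailability weighting beyond restricting PUFA scoring to EPA+DHA, and
no endpoint health-impact modelling.
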
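# nutrifu

Carbon footprints of livestock systems under nutrition-based functional
units.

Life cycle assessment (LCA) of livestock almost always reports emission
intensity per kilogram of product — liveweight, carcass weight or deboned
meat. That functional unit treats all meat as nutritionally identical,
although production systems (forage vs. concentrate feeding, lowland vs.
upland grazing, intensive vs. free-range rearing) markedly change the
nutrient content of the meat they produce. `nutrifu` is for LCA
practitioners and sustainable-food-systems researchers who want to
re-express per-kg carbon footprints per unit of *nutrition* delivered, and
to see how system rankings change when they do.

## The model

Three pieces, composable over any set of production systems:

**1. Mass-basis conversion.** A global warming potential `GWP_b` (kg
CO2-eq per kg of reference mass `b`) is rebased along the slaughter chain
liveweight → carcass → edible meat using the kill-out fraction `k` (kg
carcass per kg liveweight) and meat yield `m` (kg edible meat per kg
carcass):

    GWP_meat = GWP_LW / (k · m)        GWP_meat = GWP_CW / m

**2. Nutrient-mass functional units.** With a nutrient content `c` in
mg per 100 g meat (equivalently `c/100` g per kg), the burden per gram of
that nutrient is

    GWP_nutrient = GWP_meat / (c / 100)     [kg CO2-eq / g]

**3. Nutrient-index functional units.** A UKNI-style index scores 100 g of
meat against daily reference intakes `RDI_i`: the mean percent-of-intake
over a qualifying set `Q`, minus the mean over a disqualifying set `D`
(SFA and sodium; `D` may be empty):

    UKNI = (1/|Q|) Σ_{i∈Q} 100·c_i/RDI_i  −  (1/|D|) Σ_{j∈D} 100·c_j/RDI_j

Individual terms are deliberately not capped at 100 %. The burden per index
point (per 1 % of a day's recommended intake) is then

    GWP_index = (GWP_meat / 10) / UKNI      [kg CO2-eq per 1 % RDI]

The package ships the four standard specifications — `UKNIprot7`
(protein, MUFA, EPA+DHA, Ca, Fe, riboflavin, folate), `UKNIprot10`
(adding vitamin B12, Se, Zn) and their penalised `-2` variants — plus the
seven UK study systems (concentrate/forage beef, lowland/upland lamb,
intensive/free-range chicken, intensive pork) as plain-text fixtures, and a
seeded synthetic-study generator for property testing.

## Worked example

```r
library(nutrifu)

fx <- load_paper_fixtures()          # 7 systems + reference intakes + 4 UKNI specs

# mass-based footprints, kg CO2-eq per kg edible meat
evaluate_systems(fx$systems, functional_unit("mass_meat"))[, c("rank", "label", "value")]
#>  rank              label     value
#>     1  chicken intensive  4.400000
#>     2 chicken free_range  5.100000
#>     3     pork intensive  7.407407
#>     4   beef concentrate  9.080460
#>     5        beef forage 18.275862
#>     6       lamb lowland 26.131569
#>     7        lamb upland 30.926352

# per gram of omega-3 the beef ordering reverses: forage beef now beats
# concentrate beef by more than a factor of two
evaluate_systems(fx$systems,
                 functional_unit("nutrient_mass", nutrient = "omega3"))[1:4, c("rank", "label", "value")]
#>  rank              label     value
#>     1  chicken intensive  1.215470
#>     2 chicken free_range  2.383178
#>     3     pork intensive 14.439391
#>     4        beef forage 18.802327

# index scores, % RDI per 100 g
s <- fx$systems[[1]]                  # concentrate beef
index_score(s$nutrients, fx$specs[["UKNIprot7"]], fx$reference)
#> <index_score> UKNIprot7 = 13.58 % RDI per 100 g
```

The mass-based column says ruminant systems emit 2–7x more than poultry
per kg of meat; the omega-3 column says forage beef delivers a gram of
omega-3 for less than half the emissions of concentrate beef (18.8 vs 44.7
kg CO2-eq/g), and the index score says 100 g of concentrate beef covers on
average 13.6 % of a day's recommended intake across the seven qualifying
nutrients.

A command-line interface wraps the same functions:

```sh
inst/cli/nutrifu score     --fixtures --out results/
inst/cli/nutrifu footprint --fixtures --fu mass --fu nutrient:omega3 \
                           --fu index:UKNIprot10-2 --out results/
inst/cli/nutrifu rank      --fixtures --fu index:UKNIprot10
inst/cli/nutrifu generate  --seed 7 --n-systems 12 --out synth/
```

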
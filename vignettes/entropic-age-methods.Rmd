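---
title: "Methods: diet-driven entropy generation and entropic-age projection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diet-driven entropy generation and entropic-age projection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(entropicage)
```

## The model

`entropicage` treats the human body as an open thermodynamic system in
quasi-steady state: nutrients and oxygen enter, combustion products, urea
and heat leave, and the second-law production term — the entropy generated
inside the boundary — is what the package computes.  The pipeline has four
stages.

**Oxidation stoichiometry.**  Dietary carbohydrate, fat and protein are
represented by glucose, palmitic acid and a composite "average of the 20
amino acids" (C4.57H9.03N1.27O2.25S0.046).  Their oxidation reactions
(see `oxidation_reactions()`) route amino-acid nitrogen to urea; sulfur,
present only in the composite amino acid at S:C = 0.01, is neglected
throughout, and the reactions then balance C, H, O and N exactly (a check
run at package load and in the test suite, with a 0.3% allowance for the
rounded amino-acid coefficients).  Before conversion to moles, the diet is
scaled by a *utilization profile*: in health, digestibilities of 99%
(carbohydrate), 92% (protein) and 95% (fat); in fatty liver disease the
reduced oxidation fractions for Child–Pugh scores A (88/28/46%),
B (86/31/55%) and C (88/24/59%) replace the digestibilities — exactly one
profile applies per health state.  The unabsorbed/unoxidized dry matter is
reported as feces; 65% of produced urea is excreted at a fixed urine
concentration of 20 g/L (urine at 1 g/mL).

**Heat release.**  Per mole of fuel, the reaction enthalpy takes reactants
at 298 K and products at 310 K, `h(T) = h_form(298) + [h_sens(T) −
h_sens(298)]`, gases ideal.  Condensed species (the fuels and urea) carry
no sensible correction over the 12 K span; the shipped property table
deliberately leaves those cells empty.  Of each fuel's |ΔH_R|, the
metabolic efficiency η — glucose 0.346, palmitate 0.322, amino 0.104,
corresponding to ATP yields of 32, 106 and 8 mol/mol — is conserved as
chemical work, and the remainder `(1 − η)|ΔH_R|` leaves as heat.  The ATP
yields are exposed for reporting; the η route is the computation path.

**Entropy balance.**  Per day,
`s_gen = (Σ n s)_out − (Σ n s)_in + Q/T`,
where the out-term sums CO2, metabolic water and urea moles times their
absolute entropies at 310 K, the in-term sums fuel and O2 moles times
entropies at 298 K, and `Q` is the released heat entered as a positive
magnitude.  The sign convention is deliberate: heat export transfers
entropy to the surroundings, so the `Q/T` term *adds* to the generation
term, and `s_gen > 0` for every bundled diet under every profile (asserted
as a regression property).  Feces carry no assigned thermodynamic
properties and are excluded from the flow terms; dietary and urinary
water cancel (drinking water in, urine water out) and evaporative loss is
likewise excluded.  The annual specific rate multiplies by 365 days and
divides by the subject's mass basis.

**Lifespan projection.**  The "entropic age" is the cumulative specific
entropy since birth; the projected lifespan is the age at which it reaches
a fixed lifetime budget of 11,404 kJ/(kg K) (Kuddusi's calibration, which
with a constant metabolic entropy rate of 0.46 × 10⁻⁵ kW/(kg K) gives a
79-year life expectancy — `constant_rate_lifespan()` reproduces this).
Disease raises the effective annual rate by dividing by the one-year
survival fraction (Child–Pugh A/B/C: 0.95/0.80/0.44, following Pinter et
al.'s survival data): the surviving cohort carries the full entropy burden
over a one-year horizon.  Intermittent fasting can credit an
autophagy-linked reduction of 10–25%, applied as `rate × (1 − reduction)`;
because published plans are ambiguous about whether their rates already
include this credit, the reduction is an explicit, optional scenario
parameter rather than a default.

## Parameters that matter

| Parameter | Default | Units | Notes |
|---|---|---|---|
| digestibilities (C/P/F) | 0.99 / 0.92 / 0.95 | — | healthy absorption |
| Child–Pugh fractions | see above | — | replace digestibilities in disease |
| η (glu/palm/amino) | 0.346 / 0.322 / 0.104 | — | fraction of ΔH captured as ATP |
| urea excretion | 0.65 at 20 g/L | — , g/L | sets urine mass |
| body temperature | 310.15 | K | divisor of Q/T |
| entropy budget | 11,404 | kJ/(kg K) | lifetime limit |
| caloric multiplier | 1.2 | — | daily need = BMR × 1.2 |
| days per year | 365 | d | annualization |
| Atwater factors | 4 / 4 / 9 | kcal/g | calorie↔gram conversion |

All constants and species properties live in a plain-text table
(`inst/extdata/species_properties.csv`) plus a constants list, and every
value can be overridden key-wise via `thermo_db(overrides = ...)` (a list
or a YAML/JSON file), so a run with modified properties is fully
auditable.

## Property data and numerical choices

* **Molar masses** are fixed at the rounded values 180, 256, 119 (fuels),
  32, 44, 18, 60 g/mol (O2, CO2, H2O, urea).  These integers reproduce the
  bundled exchange anchors exactly (898 g and 613.2 g O2/day); exact IUPAC
  masses would shift results by about 0.3%.  `check_consistency()`
  verifies each stored mass against its formula within 1.5%.
* **Property table gaps.**  The adapted property set gives formation data
  for the three fuels and sensible/entropy data for the gases, but omits
  the standard formation enthalpies of CO2 and H2O, the gases' sensible
  enthalpies at 298 K, and all urea data.  Standard ideal-gas-table values
  fill these (CO2: −393,520 kJ/kmol, 9364 kJ/kmol; H2O(g): −241,820,
  9904; urea: −333,100 kJ/kmol, s = 104.6 kJ/(kmol K)); liquid-water
  properties are recorded for the urine phase though the water streams
  cancel.  The composite amino acid's entropy is specific entropy times
  molar mass: 1.401 kJ/(kg K) × 119 g/mol = 166.7 kJ/(kmol K).
* **Temperatures.**  Only 298 K (intake) and 310 K (body) are supported —
  no NASA-polynomial cp integration.  Q/T uses 310.15 K.
* **Rounding.**  Exchange masses are reported to one decimal in CSV
  output, lifespans to the nearest integer; all internal arithmetic is
  full precision, and the accumulate/project round-trip is exact by
  construction (`accumulated + rate × remaining = limit`).
* **Degenerate inputs.**  A zero diet produces an all-zero exchange row
  and zero entropy terms; a ledger whose accumulated entropy already meets
  the budget projects a lifespan equal to the starting age; a survival
  fraction of zero is an error (the adjustment is undefined), as is a
  ledger whose final segment is not open-ended.

## Design choices where the design was open

* **Diet identity over labels.**  Scenario results are keyed to diet
  *composition*, never to a plan's label: among the bundled fasting plans
  the label-to-composition assignment of published exchange values is
  internally inconsistent (the 318/99/59 g plan reproduces the oxygen
  uptake printed for the "weight gain" plan and vice versa), and keying to
  composition makes the pipeline insensitive to that.
* **Mass basis is fixed per scenario** — 100 kg for the obese/NAFLD
  scenarios, 80 kg for the fasting scenarios — and is *not* updated as
  weight changes during a diet; the divisor is the stated weight at diet
  onset.  `subject()` therefore separates `weight_kg` from
  `mass_basis_kg`.
* **One-year survival horizon.**  The disease adjustment collapses the
  general "total entropy over Δt years divided by surviving fraction
  times Δt" device to the one-year form, rate ÷ one-year survival.
* **BMR.**  Only the classic Harris–Benedict equation
  (66.5 + 13.76 W + 5.003 H − 5.755 A) is implemented, with the single
  1.2 activity multiplier; reported values are kcal/day (1 kcal =
  4.184 kJ).  Note that popular online calculators use revised
  coefficient sets and can differ by tens of kcal/day from this equation
  at the same anthropometrics.

## The synthetic diet generator

`generate_diets()` emulates the structure of guideline-constrained diet
tables: a calorie target split across macronutrients by calorie fractions
(defaults: carbohydrate 0.55, protein 0.17, fat 0.28 — the midpoints of
the adult guideline envelope of 45–65%, 10–35% and 20–35%), converted to
grams with Atwater factors 4/4/9 kcal/g, with optional multiplicative
lognormal noise of unit mean (default CV 5%, a plausible day-to-day
planning variability) so masses stay positive.  The default calorie
target of 2400 kcal/day sits at the junction of the guideline ranges for
adult women (1800–2400) and men (2400–3000).  Splits outside the envelope
are rejected unless explicitly allowed.  The generator emulates table
*structure* only: real diets have food-item composition, fibre,
micronutrients, meal timing and correlated day-to-day variation, none of
which are modelled — so passing tests demonstrate correctness of the
thermodynamic pipeline on realistic macronutrient vectors, not nutritional
realism.  `generate_subject()` provides the three study presets (80 kg /
170 cm at ages 25 and 50; a 100 kg obese subject, for whom height 170 cm
and onset age 40 are adopted as defaults since only the mass is
prescribed).

## Problem sizes in the tests

The suite exercises the pipeline on the twelve bundled diet plans under
all four utilization profiles, validates the gas exchange against an
independent atom-balance oracle on 100 random diets, and checks the
generator's mean behaviour on 1,000 draws — sizes at which every property
of interest (linearity, positivity, oracle equivalence, statistical
convergence within 3 standard errors) is already sharp.

## Known limitations

* The full-pipeline annual rate depends on the filled-in property values;
  with the shipped set the 100 kg obese plan yields ≈115 kJ/(kg K year),
  a few percent below the ≈120 figure quoted for comparable analyses
  whose property bookkeeping is not fully specified.  The package
  documents its property set precisely instead of tuning it.
* No exergy analysis, organ-level partitioning, respiratory-quotient
  dynamics, glycogen/fat storage partitioning, fibre fermentation,
  competing-risk or hazard modelling.
* The lifetime entropy budget, survival fractions and autophagy credit
  are literature calibrations, not outputs of this model; projections
  assume no diseases other than the modelled one.
* Fecal "dry matter" is a mass-balance residual, not a thermodynamic
  stream; published fecal outputs exceeding total diet mass cannot arise
  from any absorption model and are not reproduced.
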
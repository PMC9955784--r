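# entropicage

Whole-body second-law bioenergetics: from a daily diet to an annual
specific entropy generation rate, and from there to an "entropic age"
lifespan projection.

## The problem

Living bodies stay organized by importing chemical energy and exporting
entropy; the fraction of generated entropy retained in tissue is one
thermodynamic reading of ageing, and death can be modelled as the point
where cumulative specific entropy reaches a fixed lifetime budget
(11,404 kJ/(kg K)).  `entropicage` implements that accounting as a tested
pipeline for nutrition researchers and modellers: it turns diet plans
(g/day carbohydrate, protein, fat) into oxidation fluxes, heat release and
entropy generation, and projects life expectancy under healthy,
fatty-liver-disease (Child–Pugh graded) and intermittent-fasting
scenarios.

## The model

1. **Stoichiometry.** Macronutrient oxidation is represented by three
   surrogate fuels:

   - C6H12O6 + 6 O2 → 6 H2O + 6 CO2
   - C16H32O2 + 23 O2 → 16 CO2 + 16 H2O
   - C4.57H9.03N1.27O2.25S0.046 + 4.75 O2 → 3.245 H2O + 3.935 CO2 + 0.635 CH4N2O

   A utilization profile scales the diet first: healthy digestibilities
   99/92/95% (carbohydrate/protein/fat), or reduced Child–Pugh oxidation
   fractions in liver disease.  65% of the urea is excreted at 20 g/L,
   fixing the urine mass; unabsorbed dry matter leaves as feces.

2. **Energetics.** Per mole of fuel, ΔH_R = Σ n_p h(310 K) − Σ n_r h(298 K)
   with h(T) = h_f,298 + Δh_sens; a metabolic efficiency η (glucose 34.6%,
   palmitate 32.2%, amino acids 10.4%) is captured as ATP and the heat
   Q = (1 − η)|ΔH_R| is exported.

3. **Entropy balance.** At quasi-steady state,
   s_gen = (Σ n s)_out − (Σ n s)_in + Q/T with T = 310.15 K, annualized
   over 365 days per kg body mass.

4. **Lifespan.** Entropic age accumulates as rate × years; the projected
   lifespan is the age at which the 11,404 kJ/(kg K) budget is reached.
   Disease states divide the annual rate by the one-year survival fraction
   (Child–Pugh A/B/C: 0.95/0.80/0.44); intermittent fasting can credit an
   autophagy-linked 10–25% rate reduction.

## Worked example

```r
library(entropicage)
db <- default_thermo_db()
healthy <- utilization_profile("healthy", db)

# a 3100 kcal obese diet plan: 430 g carbohydrate, 150 g protein, 98 g fat
d <- as_diet(nafld_diet_table()[1, ])
exchange_table(d, healthy, db)[, c("o2_g", "h2o_g", "co2_g", "urine_g")]
#>       o2_g    h2o_g    co2_g  urine_g
#> 1 898.0114 427.8935 1081.169 1435.954

entropy_generation(d, subject(100, 170, 40), healthy, db)
#> <entropy rate 'healthy_obese'> 31.61 kJ/(K day); 115.4 kJ/(kg K year) on 100 kg
#>   terms kJ/(K day): flow out 11.254, flow in 6.977, Q/T 27.334

# Child-Pugh C at 40: keep the disease-adjusted diet or switch?
run_lifespan_scenario(list(age_start = 40, pre_onset_rate = 119.9,
                           baseline_rate = 119.9, survival_fraction = 0.44,
                           alternative_rate = 98.8), db)
#> <scenario> from age 40 with 4796 kJ/(kg K) accumulated (limit 11404)
#>   baseline    272.5 kJ/(kg K year) -> lifespan 64.2 y (64)
#>   alternative 98.8 kJ/(kg K year) -> lifespan 106.9 y (107)
#>   years gained: 42.6 (43)
```

The first call says the plan demands 898 g of O2 per day and exhales
1081 g CO2 and 428 g metabolic water.  The second closes the entropy
balance: about 31.6 kJ/K generated per day, i.e. 115.4 kJ/(kg K) per year
on a 100 kg basis, most of it carried by heat export (Q/T).  The scenario
report converts annual rates into life expectancies against the lifetime
budget: advanced liver disease without a diet change exhausts it at age
64, while the recommended diet shift projects 43 additional years.

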
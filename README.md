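# conadiet

Least-cost nutrient-adequate diets, their sensitivity to nutrient
requirements, and cross-group comparison.

## The problem

Whether a food system can deliver adequate nutrition cheaply depends on who
you are: energy and nutrient requirements differ sharply by age, sex, and
pregnancy or lactation status. The **cost of nutrient adequacy (CoNA)** for
a demographic group *g* in a country *c* is the cost of the cheapest
combination of locally priced foods that exactly meets the group's energy
requirement and stays within lower and upper bounds for 20 nutrients. It is
a lower bound on what nutrient adequacy can cost — no palatability, variety
or cultural constraints — which makes it a clean instrument for comparing
food systems and demographic groups.

`conadiet` implements the full pipeline: data model and validation,
dietary-reference-intake (DRI) constraint construction, the linear program
and its solver, shadow-price sensitivity analysis, cost normalisation and
affordability metrics, composition summaries, and country-fixed-effects
group comparisons. Because real national price collections are
access-restricted, the package includes a first-class synthetic-data
generator so every stage is testable end to end.

## The model

For foods *i* priced at *p<sub>ic</sub>* (local currency per kg as
purchased), with energy *a<sub>ie</sub>* and nutrient content
*a<sub>in</sub>* per 100 g edible portion, the diet problem is

```
min Σᵢ pᵢc · qᵢcg                       (cost, LCU/day)
s.t. Σᵢ aᵢe · qᵢcg  = EER_g             (energy balance, kcal/day)
     Σᵢ aᵢn · qᵢcg ≥ LB_ng              (19 lower bounds)
     Σᵢ aᵢn · qᵢcg ≤ UB_ng              (17 upper bounds)
     qᵢcg ≥ 0
```

Lower bounds are estimated average requirements (EAR; the harmonised
average requirement HAR for iron and zinc, reflecting low bioavailability
from plant-dominated diets), or recommended dietary allowances (RDA) in a
restrictive scenario. Upper bounds are tolerable upper intake levels (UL)
for 13 micronutrients, the chronic disease risk reduction level (CDRR) for
sodium, and acceptable macronutrient distribution range (AMDR) limits for
carbohydrate, protein and fat. Vitamin A adequacy is scored in retinol
activity equivalents while its UL applies to preformed retinol. Prices per
kg as purchased and composition per 100 g edible portion meet in the cost
coefficient `price / (10 × edible_fraction)`.

The solver is a dense two-phase simplex that returns a **vertex solution
and the dual value of every constraint**. The dual is the shadow price —
the marginal cost of tightening that requirement — and the dimensionless
**shadow-price elasticity** `e = sp × bound / CoNA` measures the percent
cost increase per 1 % increase in a requirement. Cross-group contrasts use
linear models with country fixed effects, which absorb national price
levels (including inflated costs in countries pricing short food lists).

## Worked example

```r
library(conadiet)
world <- generate_world(world_spec(n_countries = 3, seed = 11))
rq  <- build_requirement_set("F_19-30_lact", world$dri, scenario = "EAR")
sol <- solve_cona(assemble_lp(world, "C001", rq))
sol
#> <cona_solution> C001 / F_19-30_lact / EAR: optimal
#>   CoNA = 10.5580 LCU/day; 6 foods; 6 binding constraints
```

Six foods for six binding constraints: at a non-degenerate vertex optimum
the diet uses exactly as many foods as there are binding requirements.
Normalising the cost:

```r
cost_record(sol, world$countries[1, ])[, c(5, 6, 7, 8)]
#>   cona_lcu_day cona_usd_day cona_usd_per_1000kcal affordability_ratio
#> 1       10.558        0.687                 0.245               0.086
```

A lactating woman aged 19–30 in this synthetic country can meet all
requirements for $0.69/day (2017 PPP dollars), about 8.6 % of the country's
mean food spending. Which requirements drive the cost?

```r
head(sensitivity_table(sol)[order(-sensitivity_table(sol)$magnitude), ], 5)
#>      constraint shadow_price elasticity magnitude binding
#>      lb:calcium     0.004777     0.4300    0.4300    TRUE
#>          energy     0.000976     0.2588    0.2588    TRUE
#>    lb:vitamin_a     0.002117     0.1599    0.1599    TRUE
#>  lb:vitamin_b12     0.446528     0.1005    0.1005    TRUE
#>    lb:vitamin_c     0.003590     0.0325    0.0325    TRUE
```

A 1 % rise in the calcium requirement raises this diet's cost by 0.43 %;
non-binding constraints all have shadow price zero. The diet itself is
dominated by cheap starchy staples and pulses:

```r
summarize_composition(sol, world$foods)
#>                 category grams_day kcal_day weight_share energy_share
#>          starchy staples     371.8     1005        0.352        0.359
#>  pulses, nuts, and seeds     303.0     1099        0.287        0.392
#>      animal-source foods      58.7      141        0.056        0.050
#>    fruits and vegetables     280.3      122        0.265        0.043
#>            oils and fats      42.5      434        0.040        0.155
#>     sweets and beverages       0.0        0        0.000        0.000
```

## The analysis workflow

The `analysis/` directory holds numbered drivers over the package, writing
their tables under `results/`:

1. `01_generate_world.R` — synthesise the 20-country study world and write
   its foods/prices/countries/DRI CSVs.
2. `02_solve_diets.R` — solve all country × group × scenario diet LPs and
   summarise cost distributions and affordability.
3. `03_sensitivity.R` — rank requirements by mean shadow-price elasticity
   magnitude, overall and by group.
4. `04_composition.R` — composition by category and adjusted low- vs
   high-income contrasts.
5. `05_group_statistics.R` — box-plot summaries and country-fixed-effects
   adjusted group means.

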
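---
title: "Least-cost nutrient-adequate diets: model, methods, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Least-cost nutrient-adequate diets: model, methods, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conadiet)
```

## The model

The cost of nutrient adequacy (CoNA) for demographic group $g$ in country
$c$ is the optimum of a linear program over the quantities $q_{icg}$
(100 g-edible units/day) of the foods $i$ priced in that country:

$$\min \sum_i p_{ic}\, q_{icg}
\quad\text{s.t.}\quad
\sum_i a_{ie} q_{icg} = \mathrm{EER}_g,\;
\sum_i a_{in} q_{icg} \ge \mathrm{LB}_{ng},\;
\sum_i a_{in} q_{icg} \le \mathrm{UB}_{ng},\;
q \ge 0.$$

Energy is an **equality** ("energy balance"), not a range: the diet must
deliver exactly the group's estimated energy requirement. There are 19
lower bounds (3 macronutrients, 16 micronutrients — sodium has none) and
17 upper bounds (3 AMDR limits, 13 tolerable upper intake levels, the
sodium CDRR). Quantities are non-negative and continuous; there are no
palatability, variety or food-group constraints, deliberately — CoNA is a
lower bound on the cost of adequacy, not a diet recommendation.

Units meet in the cost coefficient. Prices arrive per kg as purchased;
composition is per 100 g **edible** portion. The cost of one decision unit
(100 g edible) is therefore $p_{ic} / (10\,e_i)$, with $e_i \in (0,1]$ the
edible fraction. Solutions are reported in grams/day (units × 100).

## Requirement construction

`build_requirement_set()` applies the dietary-reference-intake rules per
group and scenario:

* **Scenario "EAR"** (baseline): lower bounds are estimated average
  requirements, the median of a healthy population's need. **Scenario
  "RDA"**: recommended dietary allowances, covering 97.5 % of each group.
* **Iron and zinc** use $\max(\mathrm{HAR}, \text{scenario value})$: the
  harmonised average requirement raises the average to reflect the low
  bioavailability of these minerals from the plant-dominated foods that
  least-cost diets select. We keep the $\max$ under the RDA scenario too —
  the bioavailability argument does not vanish when the population
  coverage target tightens, and the $\max$ preserves
  $\mathrm{LB}^{RDA} \ge \mathrm{LB}^{EAR}$.
* **Macronutrients**: AMDR fractions of energy convert to grams/day with
  Atwater factors (4 kcal/g carbohydrate and protein, 9 kcal/g fat) — the
  standard conversion, used consistently in the synthetic generator so the
  energy equality and the AMDR windows are jointly satisfiable. Protein
  and carbohydrate also carry gram-denominated average requirements;
  since both constraints must hold, the lower bound is the $\max$ of the
  two (imposing both is equivalent to imposing the max). Fat has AMDR
  bounds only.
* **Vitamin A** is one nutrient with two composition columns: adequacy is
  scored against retinol activity equivalents (carotenoids count), while
  the toxicity UL applies to preformed retinol only. The LP therefore has
  a vitamin A lower row and upper row reading different columns, and the
  usual LB ≤ UB check is skipped for this pair.
* **Sodium** appears only as an upper bound (the CDRR).

DRI values are **inputs** via `dri.csv`, not hard-coded: reference tables
are published at full precision elsewhere and hard-coding a partial copy
would invite silent staleness. The packaged
`synthetic_dri_table()` provides a complete, internally consistent table
(EAR ≤ RDA ≤ UL everywhere) with plausible magnitudes and the physiology
that matters for the analysis — higher calcium in adolescence and old age,
higher iron for women of reproductive age and pregnancy, higher folate in
pregnancy, higher vitamins A and C in lactation, energy peaking for
adolescent boys and lactating women — but it is synthetic and claims no
fidelity to any published table.

## The solver

The LP engine (`lp_solve()`) is a dense full-tableau two-phase primal
simplex written for this package. The choice is deliberate rather than a
convenience: the analysis needs (a) **dual values** for every row, because
shadow prices are the output of interest, and (b) a **basic (vertex)
solution**, because the "foods used = binding constraints" accounting
identity only holds at a vertex; interior-point solutions satisfy neither.
Diet problems are small — 37 rows by 40–260 columns — so dense algebra is
appropriate and each solve takes milliseconds.

Numerical choices:

* pivot/feasibility tolerance $10^{-9}$; phase-1 infeasibility declared
  above $10^{-7}$;
* Dantzig (most-negative reduced cost) pricing with a switch to Bland's
  rule after $2(m+N)$ iterations, guaranteeing termination on degenerate
  instances; ratio-test ties break toward the smallest basis index;
* duals are recovered exactly from the final basis as
  $y^\top = c_B^\top B^{-1}$ (solved, not read off the tableau), so
  complementary slackness holds to machine precision;
* binding constraints are detected at relative tolerance $10^{-6}$ scaled
  by $\max(1, |\mathrm{rhs}|)$; equality rows are always binding;
* infeasibility is a **status**, not an error: countries with short food
  lists can genuinely fail the constraint system (e.g. no vitamin B12
  source), and the pipeline records the cell rather than aborting.

At degenerate optima the dual vector is not unique. The package reports
the solver's dual and exposes `finite_difference_elasticity()` as an
independent check; tests flag disagreement beyond tolerance rather than
averaging bases, which would fabricate precision.

Two independent oracles check the solver: brute-force vertex enumeration
(`lp_enumerate()`, all $\binom{m+n}{n}$ candidate bases on small random
instances) and the `boot` package's simplex on the same instances.

## Sensitivity analysis

The shadow price of constraint $j$ is its dual $sp_j$: the marginal cost
of tightening the bound, in LCU per constraint unit; non-binding
constraints have shadow price exactly zero. The headline, unit-free
quantity is the **shadow-price elasticity**
$e_j = sp_j \cdot \mathrm{rhs}_j / \mathrm{CoNA}$ — the percent change in
diet cost per 1 % change in the requirement. For upper bounds the raw
elasticity is non-positive (relaxing the cap cannot raise cost); the
reported headline is its magnitude, with the sign retained. The energy
elasticity may take either sign: more energy means more food, but also
licenses cheap energy-dense items.

Reported elasticities are dual-based — exact and local, and three orders
of magnitude cheaper than re-solving every constraint of every cell. The
finite-difference route (re-solve at $\mathrm{rhs}\times(1\pm\delta)$,
central difference, default $\delta = 0.01$ matching the literal "1 %
change") exists as a verification oracle. Because the optimal value is
piecewise linear in any single bound, the two agree exactly whenever no
basis change occurs within the interval; the tests assert agreement at
$10^{-4}$ and fall back to one-sided differences (with a warning) when a
perturbation is infeasible.

## Metrics and reporting conventions

Costs are computed in nominal local currency and converted to 2017
international dollars with PPP factors; cost per 1000 kcal
($\mathrm{CoNA} / (\mathrm{EER}/1000)$) compares diet composition on an
energy-adjusted basis, since total food volume varies greatly across
groups. The affordability ratio divides CoNA by observed national food
expenditure per capita per day; values above 1 mean the cheapest adequate
diet exceeds mean food spending. The poverty food budget defaults to 63 %
of a $2.10/day line ($1.32/day), both arguments rather than constants.
Report rounding is 2 decimals for \$/day and \$/1000 kcal and 1 decimal
for percents; full precision is retained internally.

Composition summaries aggregate optimal quantities into six categories
(starchy staples; pulses, nuts, and seeds; animal-source foods; fruits and
vegetables; oils and fats; sweets and beverages). Categories never enter
the optimisation; a country lacking a category is flagged, not rejected.

## Statistics

Box-plot summaries use linear-interpolation quantiles (R type 7 — the
convention is documented because several exist) and the notch half-width
$1.58 \times \mathrm{IQR}/\sqrt{N}$. Cross-group comparisons fit
$y_{cg} = \alpha_g + \gamma_c + \varepsilon$ by OLS with a country
indicator absorbing all cross-country variation; the saturated
group-indicator parameterisation spans the same space as sex × age
interactions. Adjusted group means are $\hat\alpha_g$ plus the average
country effect, with classical homoskedastic 95 % CIs (the plain "95 % CI
from a fixed-effects regression" convention; no clustering or robust
errors by default, and no multiple-testing correction since plain CIs are
the reporting unit). The income contrast regresses category grams on
income-class indicators with demographic-group fixed effects.

## The synthetic world

`generate_world()` emulates the *structure* of international price
collections, not any country's numbers:

* a master list of ~200 items in six categories; each country prices each
  item with probability 0.625, so countries average ~125 priced items with
  realistic spread, and every country is guaranteed ≥ 1 item per category
  (bounded retries, then a forced addition with a warning);
* nutrient densities drawn from mean-preserving log-normal noise
  (sdlog 0.35) around category archetype profiles — cheap calories in
  staples, protein/iron/folate in pulses, calcium/B12/retinol exclusively
  in animal-source foods, vitamin C and carotenoid vitamin A in produce,
  vitamin E in oils. Energy is set to the Atwater sum
  $4C + 4P + 9F$, making macronutrient shares internally consistent with
  the energy equality;
* prices are log-normal around category base levels (staples cheapest per
  kg, animal-source foods dearest), with item-level, country-level and
  country × item dispersion, a country price level, and PPP factors
  linking LCU to international dollars; animal-source foods carry an
  income-graded relative-price multiplier (dearer where incomes are
  lower), which reproduces the qualitative substitution toward pulses and
  produce in poorer countries;
* food expenditure per capita is income-graded; population is log-normal.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: actual price levels or cross-country price
correlations (synthetic cost levels are not comparable to estimates from
real price collections — only the structural and qualitative properties
carry over); within-category
heterogeneity of real food types (a single archetype per category, so
e.g. "dairy vs meat" structure inside animal-source foods is absent);
seasonal or sub-national variation; correlated missingness of items
(availability is independent Bernoulli); and measured nutrient
composition of any real food. Conclusions from this package about real
food systems require real price and composition inputs through the same
CSV schemas.

Missing composition values load as zero with a warning: conservative for
lower bounds (a zero can only make adequacy harder), but it means users
must supply complete tables for upper bounds they care about.

## Problem sizes

The test-suite and acceptance computations use worlds of 2–20 countries
(40–800 LPs), 200 random solver-vs-enumeration instances with ≤ 4 foods,
and 200 simulated panels for CI coverage — sizes chosen so the full
pipeline exercises every code path in a few minutes on one core while
keeping Monte-Carlo error small relative to the tolerances tested (e.g.
binomial SE ≈ 1.5 % for coverage at $n = 200$).

## Known limitations

* One price and one composition vector per item per country; no
  uncertainty propagation through composition or requirements.
* Alternative optima are solver-dependent; tests assert objective values
  and feasibility, never the specific food mix, except on fixtures with
  unique optima.
* The fixed-effects comparison assumes additive country effects on the
  cost scale; a multiplicative (log-scale) specification would be a
  reasonable alternative and is not provided.
* The dense simplex is built for this problem's scale; it is not a
  general-purpose LP library (no sparsity, no bounded variables, no
  presolve).
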
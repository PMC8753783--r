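Package: conadiet
Title: Least-Cost Nutrient-Adequate Diets and Their Sensitivity to Requirements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the cost of nutrient adequacy (CoNA): the least-cost
    daily diet meeting an energy-balance equality and lower/upper bounds for
    20 nutrients, for 20 demographic groups defined by age, sex, and
    reproductive status. Assembles and solves the diet linear programs with a
    two-phase simplex that returns dual values and a basic (vertex) solution,
    derives shadow prices and shadow-price elasticities of diet cost with
    respect to each requirement, normalises costs by purchasing power parity
    and by energy, summarises diet composition across six food categories,
    and compares demographic groups with country-fixed-effects linear models.
    Includes a synthetic-data generator emulating national food price tables
    so that every pipeline stage is testable without access-restricted price
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    boot,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
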
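Package: nutristock
Title: Nutritional Assessment and Purchase Planning of Emergency Food Stockpiles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for evaluating whether a municipality's emergency food
    stockpile meets the nutritional needs of an estimated disaster-affected
    population. Computes population-weighted dietary reference intakes per
    sex and age group, scales them by victims and stockpile days, compares
    them with the nutrient supply of an inventory of catalogued foods, and
    reports per-nutrient excess/deficiency ratios, pass/fail marks, and the
    number of people covered by current stock. Includes a reduced
    five-nutrient shelter profile (energy, protein, vitamins B1, B2 and C),
    filtering of food catalogues to genuinely stockpilable items, and
    greedy and linear-programming purchase planners that recommend what and
    how much to buy to close per-nutrient deficits under budget and storage
    constraints. Ships seeded synthetic-data generators and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    optparse,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
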
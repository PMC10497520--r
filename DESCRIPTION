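Package: foodshift
Title: Partial-Equilibrium Scenario Analysis of Plant-Based Substitution of
    Animal-Source Foods
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A stylized recursive-dynamic partial-equilibrium model of the
    global food system for analysing scenarios in which animal-source foods
    (beef, chicken, pork, milk) are progressively substituted by novel
    plant-based alternatives built from ingredient-share recipes.  Includes a
    seeded generator of synthetic world baselines (13 macro regions, 18 crops,
    7 animal products), a quadratic-programming market equilibrium solver
    (welfare maximization with endogenous prices, land allocation and trade),
    a six-dimension scenario engine, recipe accounting with Amino Acid Score
    protein-quality checks, greenhouse-gas / nitrogen / water accounts,
    afforestation carbon cohorts with Biodiversity Intactness Index recovery,
    and log-normal prevalence-of-undernourishment metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    quadprog,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
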
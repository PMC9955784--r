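Package: entropicage
Title: Diet-Driven Metabolic Entropy Generation and Entropic-Age Lifespan Projection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Whole-body second-law bioenergetics from diet composition.
    Converts daily macronutrient intake into oxidized fuel moles via the
    oxidation stoichiometry of glucose, palmitic acid and an average amino
    acid, computes respiratory gas exchange and nitrogen excretion,
    evaluates heat release from reaction enthalpies and metabolic
    efficiencies, and closes an open-system entropy balance at body
    temperature to obtain the annual specific entropy generation rate.
    Projects lifespan against a fixed lifetime entropy budget ("entropic
    age"), with Child-Pugh survival-fraction adjustments for fatty liver
    disease and intermittent-fasting scenario comparison, and generates
    guideline-constrained synthetic diet plans for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
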
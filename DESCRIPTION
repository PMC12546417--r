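Package: nppu
Title: Net Primary Production Use Characterization Factors for Feed Ingredients
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the Net Primary Production Use (NPPU, also called Biotic
    Resource Use) life-cycle-assessment indicator for feed ingredients, in kg
    of primary-production carbon appropriated per kg of ingredient. Covers
    carbon content from proximate composition via empirical-formula
    stoichiometry, trophic amplification after Pauly and Christensen with
    tiered generic/specific parameter policies for marine, freshwater,
    other-animal, milk and plant ingredient classes, fishmeal/fish-oil
    coproduct allocation by mass, energy or user weights, first-order Taylor
    propagation of input standard deviations with a Monte-Carlo cross-check,
    and readers, writers and validators for the reference CSV table layouts,
    plus a synthetic-fixture generator and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
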
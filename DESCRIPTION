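Package: aathermo
Title: Thermodynamics of Amino Acid Protonation, Solubility and Weak
    Complexation in Electrolyte Media
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models the ionic-strength and temperature dependence of the
    stepwise protonation constants of alpha-amino acids with a specific ion
    interaction (SIT) extended Debye-Hueckel treatment combined with the
    Clarke-Glew temperature expansion; analyses total and specific
    solubility against supporting-electrolyte concentration via Setschenow
    coefficients and derives solubility products; and quantifies weak
    cation-ligand ion pairs from the depression of apparent protonation
    constants in an interacting medium relative to a weakly interacting
    baseline (the delta-pK method). Ships evaluated parameter sets for
    glycine, alanine, valine, leucine, serine and phenylalanine in NaCl and
    tetramethylammonium chloride media, weighted least-squares refitting of
    measurement data, concentration-scale conversion, speciation
    calculations and a seeded synthetic-data generator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
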
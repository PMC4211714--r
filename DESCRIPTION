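Package: gdsub
Title: Gene-Diet Interaction Analysis with Macronutrient Substitution Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying whether genetic predisposition to adiposity
    modifies the association between dietary protein and subsequent change in
    body weight or waist circumference. Implements unweighted risk-allele
    predisposition scores over an annotated SNP panel, isocaloric macronutrient
    substitution regression models (leave-one-out and reparameterized
    substitution-variable forms) with true substitution-by-score interaction
    terms, annualized anthropometric-change outcomes, inverse-variance fixed
    and DerSimonian-Laird random-effects meta-analysis with heterogeneity
    statistics, Bonferroni-corrected per-SNP interaction scans, energy-balance
    subgroup summaries, and a multi-cohort synthetic-data generator with
    planted effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor
Config/testthat/edition: 3
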
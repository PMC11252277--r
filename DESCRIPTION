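Package: saprolens
Title: Protozoan Plankton Bioassessment of Running Waters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for bioassessment of rivers from planktonic protozoan
    communities: conversion of Sedgwick-Rafter counting-chamber observations
    to concentrations, geometric biovolume and dry-weight biomass estimation,
    diversity and frequency-weighted dominance indices, the Pantle-Buck
    saprobic index with water-quality classification, and
    community-environment matching via Ward clustering, Mantel-type matrix
    correlation (RELATE) and exhaustive best-subset selection of
    environmental variables (BIOENV). Ships transcriptions of a published
    six-site Nile River survey as worked fixtures and a seeded simulator of
    monitoring campaigns with planted pollution gradients for method
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    vegan,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
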
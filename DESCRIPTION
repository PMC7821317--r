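Package: oppsel
Title: Sex-Specific Opportunity for Selection Under Sex-Limited Stress
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individual-based simulation of sex-specific opportunity for
    selection (Crow's I, the variance in relative fitness) when environmental
    stress inflates the variance of individual condition in one or both sexes.
    Reproduction is resolved in mating groups of two females and two males:
    female fecundity scales with female condition and males split the group's
    total fecundity through a contest success function. Optional model variants
    add female-female competition, sperm limitation, male harm and nuptial
    gifts. A companion estimation pipeline computes mean-standardized fitness,
    per-group opportunity for selection with an assay-date variance component
    (one-way random-effects method of moments), bootstrap intervals for the log
    male/female variance ratio, treatment contrasts and skewness from tabular
    fitness-assay data, and a synthetic-data generator produces assay tables
    with known ground truth for parameter-recovery checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    e1071
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
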
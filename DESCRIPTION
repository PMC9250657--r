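Package: hexaHWE
Title: Asymptotic Hardy-Weinberg Equilibrium and Double Reduction Tests for Autohexaploids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gamete-transmission modelling and statistical testing for
    biallelic markers in autohexaploid populations under polysomic
    inheritance. Implements the triploid-gamete segregation model with
    double reduction, the random-mating recursion by which hexaploid
    genotype frequencies approach asymptotic Hardy-Weinberg equilibrium
    (aHWE) over 8-9 generations, chi-square and likelihood-ratio tests
    for aHWE and for the presence of double reduction (including
    collapsed three-class variants for dosage-ambiguous markers),
    EM estimation of gamete and parental genotype frequencies, and a
    seeded Monte-Carlo engine for power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
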
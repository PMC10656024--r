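Package: igtransfer
Title: Mechanistic Simulation of Transplacental IgG Transfer and Prenatal
    Immunization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A compartmental mass-action simulator of maternal-fetal
    immunoglobulin G (IgG) transport across the placenta. Four IgG
    subclasses are carried through five compartments (maternal blood,
    syncytiotrophoblast endosomes, villous stroma, fetal endothelial
    cells, fetal blood) by FcRn- and FcgRIIb-mediated transcytosis with
    gestation-dependent receptor expression. The package also provides a
    Transwell endothelial (HUVEC) transcytosis model with a closed-form
    receptor-competition solution, a plasma-cell vaccine-response model
    coupled into the maternal compartment for in silico prenatal
    immunization experiments (timing, dosage, and Fc-affinity scenarios),
    iterative pass/fail calibration of the free parameters against
    longitudinal fetal IgG targets, and Latin-hypercube global
    sensitivity analysis via orthogonalized partial least squares
    regression with variable-importance-in-projection scores.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    mixOmics,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
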
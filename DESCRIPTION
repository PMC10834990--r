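Package: debipm
Title: Dynamic Energy Budget Integral Projection Models for Ectotherm Life Histories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds dynamic energy budget integral projection models (DEB-IPMs)
    from eight life-history traits per ectotherm species (lengths at birth,
    puberty and maximum size, juvenile and adult mortality rates, von
    Bertalanffy growth rate, maximum reproduction rate, and the energy
    allocation fraction kappa). The length-structured kernel is discretized
    into a projection matrix from which the package computes population growth
    rate, demographic resilience (damping ratio), net reproductive rate,
    generation time and a further set of derived life-history traits (Keyfitz
    entropy, age at maturity, mature life expectancy, growth directionality,
    recruitment success, degree of iteroparity) via age-from-stage methods.
    Includes trait-table I/O in the DEBBIES schema, closed-form trait
    estimators for data-poor species, trait elasticities of the growth rate,
    feeding-level sweeps with feasibility diagnostics, and the no-intercept
    regression statistics used to compare predicted against observed
    life-history values.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
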
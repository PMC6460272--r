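Package: uvkin
Title: UV Survival Kinetics and Categorical Statistics for Plate-Count
    Irradiance Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: First-order microbial UV-inactivation kinetics with an explicit
    fluence term (transmittance x bandwidth x intensity x time): estimation of
    the survival constant from colony-forming-unit time series by log-linear
    least squares, half-life and time-to-threshold calculations, and
    conversion between optical density and transmittance.  Includes the
    categorical statistics battery commonly applied to isolate phenotype and
    treatment data (Yates-corrected chi-square, Fisher's exact test,
    Kruskal-Wallis, balanced two-way ANOVA with interaction), a seeded
    synthetic-data generator emulating plate-count irradiance experiments
    with Poisson counting noise, CSV readers and writers for the survival,
    contingency and treatment-grid dialects, and a reproducible pipeline
    driver with a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
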
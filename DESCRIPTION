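Package: bcbcr
Title: Bioactive Concentration to Blood Concentration Ratio Screening for PFAS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screening-level risk prioritization of per- and polyfluoroalkyl
    substances (PFAS) by comparing human biomonitoring blood concentrations
    with in vitro bioactivity. Harmonizes heterogeneous biomonitoring summary
    records (whole blood, serum, plasma, cord matrices) to plasma-equivalent
    concentrations, aggregates endpoint-level in vitro assay results into
    per-technology and chemical-level points of departure (PODs), computes the
    Bioactive Concentration to Blood Concentration Ratio (BCBCR) per chemical,
    population and metric, ranks chemicals, and compares in vitro PODs with
    plasma concentrations at in vivo rat effect levels. Includes a synthetic
    data generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    withr,
    ggplot2,
    stats,
    utils,
    ChemmineR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
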
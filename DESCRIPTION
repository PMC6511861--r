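Package: ppgppalloc
Title: Proteome Allocation Analysis of ppGpp-Perturbed Bacterial Growth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for steady-state growth physiology of Escherichia
    coli under titrated (p)ppGpp levels. Reduces raw assays to physiological
    quantities (exponential growth rates from OD600 time series, Miller units
    from beta-galactosidase colorimetry, translational elongation rates from
    LacZ induction kinetics, active ribosome fractions from flux balance),
    implements a three-sector proteome allocation model with a flux-limited
    growth predictor for forced ribosomal allocation, fits linear growth laws
    (RNA/protein ratio and promoter activity versus growth rate), recovers
    allocation parameters from two-direction titration data, and generates
    complete synthetic titration experiments from known parameters so that
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
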
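Package: hrequity
Title: Equity and Efficiency Analysis of Regional Health Resource Allocation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the equity and efficiency of health resource
    allocation across the regions of a province or comparable administrative
    unit. Equity is measured with Lorenz curves and Gini coefficients under
    either a population or a geographic-area allocation base, and with the
    health resource density index (HRDI) and its standardised form W, which
    combine per-capita and per-area densities. Efficiency is measured with
    input-oriented data envelopment analysis (DEA): overall (CRS), technical
    (VRS) and scale efficiency, two-phase slack maximisation, peer weights and
    returns-to-scale classification, solved with a built-in exact simplex
    method. A synthetic panel generator with controllable Gini targets and
    DEA sets with planted efficiencies supports testing and power analysis,
    and a pipeline driver reproduces the standard table and figure layouts of
    provincial equity-and-efficiency studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
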
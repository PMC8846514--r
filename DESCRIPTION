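Package: geosample
Title: Geographic Representation Audits of Public Sequence-Sample Metadata
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for auditing where public human-microbiome sequencing
    samples come from. Parses BioSample-style XML metadata and SRA
    RunInfo-style run tables, restricts records to human-microbiome
    samples via taxonomy-ID body-site mapping and host-value screening,
    resolves free-text geographic attributes to countries, United Nations
    SDG regions, and least-developed-country status, and computes
    representation statistics: per-country and per-region sample shares,
    population-normalised representation proportions, a signed scaled
    representation index for choropleth mapping, and release-date time
    series. Includes a seeded synthetic-cohort generator with known
    ground truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    ggplot2,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
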
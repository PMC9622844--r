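Package: arcticseb
Title: Harmonization and Analysis of Arctic Surface Energy Budget Observations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to harmonize sub-daily flux-tower observations of the Arctic
    surface energy budget (SEB) into quality-controlled daily series, derive
    site-level SEB drivers (continentality, summer warmth, snow amount and
    phenology), rank driver importance with an all-pairs variance-partitioning
    scheme, estimate per-vegetation-type flux magnitudes with linear mixed
    models, and characterize flux seasonality as summer-regime timing relative
    to snow phenology. A seeded synthetic-data generator emulates the
    multi-site, multi-network observation structure so the whole pipeline runs
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    rlang,
    readr,
    lubridate,
    stats,
    lme4,
    lmerTest,
    emmeans
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
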
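Package: pufanon
Title: Suppression-Only Anonymization of Categorical Registry Microdata
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A statistical-disclosure-control toolkit for preparing public
    use files (PUFs) from categorical registry microdata, built around the
    anonymization strategy used for open COVID-19 cohort releases:
    qualitative key-variable scoring, k-anonymity, t-closeness with a
    hierarchy-aware earth mover's distance, a minimum value-frequency rule,
    and a suppression-only fixpoint engine that is safe under continuous
    release of a growing registry. Includes a synthetic registry generator,
    prosecutor re-identification risk profiling, and before/after output
    quality reporting (distribution bias, case fatality rate, age-death
    association).
License: MIT + file LICENSE
Encoding: UTF-8
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
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
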
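Package: clivdr
Title: Interval-Valued Chronic Liver Disease Risk from Longitudinal Health Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes interval-valued 10-year chronic liver disease (CLivD score)
    risk for longitudinal patient event streams with missing inputs. Missing risk
    factors are substituted by their extreme default values to obtain a minimum
    and maximum risk; the width of the resulting risk interval measures assessment
    precision. Includes parameter-lifecycle resolution of time-stamped
    measurements, enrichment of inputs from ICD-10/ICPC-2 diagnosis codes and
    rule-based Finnish free-text extraction, low/moderate/high/not-specified risk
    categorization, waist-hip-ratio data-availability scenario simulation, and a
    synthetic cohort generator emulating the marginal statistics of a national
    electronic health record repository.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr (>= 1.1.0),
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
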
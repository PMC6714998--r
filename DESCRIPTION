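Package: costpyramid
Title: Cost Acuity Pyramid Segmentation and Patient Flow Analysis for
    Longitudinal Health Care Cost Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analyse longitudinal patient-year health care cost panels the
    way population health analytics teams do: segment each fiscal year's
    utilizers into top 5% / middle 45% / bottom 50% cost tiers (the cost
    acuity pyramid), estimate year-to-year Markov transition matrices of
    patient flow between tiers, account for the dollars attached to origin
    cohorts and to up/stay/down movement groups, test linear trends in
    annual cost totals, and compare movement groups on demographic and
    clinical attributes. A seeded synthetic-panel generator with latent
    segment dynamics and heavy-tailed lognormal costs lets the whole
    pipeline run and be tested without access to any protected data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
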
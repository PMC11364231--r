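Package: fintox
Title: Financial Toxicity of Acute Injury Care from Itemized Hospital Costs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the financial toxicity of acute-injury hospital
    care in low-resource settings. Builds per-patient out-of-pocket (OOP)
    expenses from an itemized fee schedule (consultations, procedures, imaging,
    ward stay, consumables, death expenses) with substitution rules for
    under-specified imaging; classifies each patient against WHO-style
    catastrophic health expenditure thresholds (10% and 25% of total household
    expenditure, 40% of non-subsistence expenditure) and impoverishment poverty
    lines (Tanzanian national line, $1.90/day, $3.20/day) using the
    OECD-modified equivalence scale; generates reproducible synthetic trauma
    cohorts for testing; and renders stratified descriptive tables and a
    Three-Delays prehospital pathway summary.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
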
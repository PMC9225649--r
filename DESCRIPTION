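Package: dupcua
Title: Decision-Tree and Markov Cost-Utility Model of Dupilumab for Severe
    Chronic Rhinosinusitis with Nasal Polyps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a cost-utility model comparing dupilumab added to best
    supportive care (BSC) against BSC alone in adults with severe uncontrolled
    chronic rhinosinusitis with nasal polyps (CRSwNP), from the Italian payer
    perspective. A one-year decision tree with response assessments at weeks 24
    and 52 feeds a lifetime annual-cycle Markov cohort model over five alive
    health states plus death. The package values discounted quality-adjusted
    life years and a cost breakdown (drug acquisition, disease management
    including surgery, adverse events, productivity losses), computes the
    incremental cost-utility ratio and net monetary benefit, and provides
    one-way (tornado) and probabilistic sensitivity analysis with moment-matched
    gamma, beta and truncated-normal distributions, cost-effectiveness
    acceptability curves, and societal-perspective and reduced-compliance
    scenario analyses. Inputs the source trials did not publish (arm-specific
    response probabilities, the mortality schedule, the per-administration drug
    price, workdays lost per state) are generated as clearly watermarked
    synthetic placeholders so the full pipeline runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
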
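Package: miamarkov
Title: Markov Decision Model for Small Unruptured Multiple Intracranial Aneurysms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic Markov cohort model comparing six management
    strategies for patients harbouring two small (<7 mm) unruptured intracranial
    aneurysms: natural history, prophylactic coiling of one or both aneurysms,
    and imaging follow-up at annual, biennial or five-yearly intervals. The
    nine-state annual-cycle model accumulates discounted quality-adjusted
    life-years and supports base-case evaluation, probabilistic sensitivity
    analysis with moment-matched beta, lognormal and triangular parameter
    distributions, one-way (tornado and threshold) analyses, and two-way
    sensitivity region mapping. Includes a Gompertz life-table fixture and a
    synthetic patient-level cohort generator for fully reproducible analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
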
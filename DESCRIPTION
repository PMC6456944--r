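Package: cvccea
Title: Cost-Effectiveness of Ultrasound-Guided Central Venous Catheterization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Decision-analytic cost-effectiveness model comparing
    ultrasound-guided and landmark-based central venous catheterization of
    the internal jugular vein. Implements a three-attempt decision tree with
    per-attempt failure and complication probabilities, expected-cost and
    effectiveness rollback, incremental cost-effectiveness with dominance
    verdicts, deterministic (tornado) and probabilistic (Monte Carlo)
    sensitivity analyses with moment-matched beta and gamma distributions,
    structural scenario analyses, intervention-cost threshold analysis,
    payer-level budget impact projection, and a patient-level
    microsimulation used as an independent oracle for the analytic tree.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
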
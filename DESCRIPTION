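Package: carat
Title: Computerized Antithrombotic Risk Assessment for Atrial Fibrillation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Decision support for antithrombotic therapy selection in elderly
    patients with atrial fibrillation. Implements CHADS2 stroke-risk and
    HEMORR2HAGES bleeding-risk scoring with configurable risk banding, a
    rule-based therapy recommendation cascade (CARAT) with medication-safety
    flags, a taxonomy of therapy transitions (upgrade, side-step, downgrade,
    dose adjustment), chance-corrected agreement statistics (Fleiss kappa)
    between recommendations and prescriber decisions, the statistical layer of
    a cluster-randomized prescribing trial (arm comparisons, univariate
    screening, forward stepwise Wald logistic regression, pseudo R-squared),
    and a synthetic cohort generator with general-practitioner clustering at a
    configurable intracluster correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    sandwich
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
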
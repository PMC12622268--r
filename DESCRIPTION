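Package: plaquekit
Title: Intracoronary OCT Plaque Morphometry, Artifact Correction and
    Agreement Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale toolkit for intravascular optical coherence
    tomography (OCT) pullback analysis. Provides lumen-centered polar
    resampling, histogram-matching correction of the effect of imaging
    artifacts (gas bubbles, signal dropout) on the vessel wall, mask-based
    plaque morphometry (lumen area, lipid and calcium arcs, fibrous-cap
    thickness), rule-based plaque classification with high-risk flagging
    (thin-cap fibroatheroma and related phenotypes), an agreement and
    noninferiority statistics battery (intraclass correlation for absolute
    agreement, Bland-Altman limits of agreement, diagnostic performance,
    Wald-type asymptotic noninferiority with continuity correction), a
    synthetic phantom pullback generator with analytic ground truth, and a
    desk-scale segmentation training harness with a hybrid Dice and
    cross-entropy loss.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
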
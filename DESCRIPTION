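Package: dtec
Title: Doubling-Time Energy Conversion Analysis of Tumor Growth Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analyzes control/treated tumor-volume trajectories from xenograft
    studies under an exponential growth model. Converts doubling times into
    per-cell growth energies (the DT-EC map), aggregates them into total tumor
    energies (histologic grade) and per-regimen dose-energy yields, applies a
    virtual-growth transform to shrinking tumors so the energy map stays
    defined, scores regimen efficiency from the intraday doubling time at dose
    delivery, and fits a linear dose-energy model for predicting docetaxel
    response. Includes a transcription of the underlying treatment table and a
    synthetic-cohort generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
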
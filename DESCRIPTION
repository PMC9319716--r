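Package: pedreli
Title: Test-Retest Reliability of Plantar-Pressure Insole Gait Variables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for test-retest reliability analysis of pedobarographic
    (plantar-pressure insole) gait data, with an emphasis on children with
    cerebral palsy. Provides a synthetic insole-recording generator with
    known variance structure, stance-phase footprint detection and cleaning,
    whole-foot and three-zone (hindfoot, midfoot, forefoot) masking, the six
    standard pedobarographic variables (force-time integral, pressure-time
    integral, maximum force, peak pressure, contact area, contact time), and
    reliability statistics: two-way absolute-agreement average-measures
    intraclass correlation with exact F-based confidence intervals,
    Bland-Altman limits of agreement, standard error of measurement, and
    minimal detectable change, including percentage forms and qualitative
    bands.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
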
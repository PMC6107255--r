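Package: marmact
Title: Actigraphy, Sleep and Circadian Rhythm Analysis for the Marmoset
    Model of Parkinson's Disease
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing collar-accelerometer activity counts from
    common marmosets in studies of MPTP-induced parkinsonism.  Reads and
    writes epoch-level activity series, scores the nocturnal window into
    sleep and wake bouts and computes eight sleep-quality metrics, derives
    the nonparametric circadian rhythm indices (inter-daily stability,
    intra-daily variability, L5, M10, their onsets and relative amplitude),
    summarises diurnal activity and detects the activity pulse that follows
    an L-DOPA dose, scores the nonhuman-primate Parkinson's disease rating
    scale, the object-retrieval task with barrier detour and head-tremor
    oscillation counts, and generates seeded synthetic rest-activity records
    emulating baseline, lesioned and dosed conditions so every stage can be
    validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
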
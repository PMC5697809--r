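Package: urbanrhythm
Title: Urban Circadian Rhythms from Mobile Phone Calling Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers population-level circadian rhythms of cities from call
    detail records (CDRs). Builds daily calling-activity distributions (all
    calls, first call of the morning, last call of the night), quantifies
    timing delays between cities by Kullback-Leibler divergence minimization
    over a discrete shift grid, compares calling-activity phases against
    solar cues (sun transit, solar midnight) from a built-in low-precision
    ephemeris, and estimates age- and gender-resolved low-activity periods
    and mid-sleep times. Includes a synthetic CDR generator with known
    ground truth for parameter-recovery testing, since real CDR datasets
    are typically access-restricted.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    geosphere,
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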
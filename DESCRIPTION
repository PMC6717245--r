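Package: whalecues
Title: Cue-Rate Estimation for Migrating Gray Whales from Acoustic,
    Infrared, and Visual Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Converts counts of gray whale cues (acoustic M3 calls and
    infrared-detected blows) into per-whale cue rates by combining them
    with visually derived daily abundance, the offshore distribution of
    migrating whales, and the mean time a whale spends inside each
    sensor's search area. Includes detection-probability corrections
    (Monte Carlo probability of acoustic localization, effort-gap
    corrections, camera effective-detection-range estimation),
    shore-based camera georeferencing (pixel to range/azimuth to
    position on a spherical earth), a two-term power model of the daily
    calling rate with pointwise prediction intervals, inversion of cue
    rates to back-estimate whale numbers during unsurveyed periods, and
    a synthetic-data generator emulating the migration's statistical
    structure so every stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    geosphere,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
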
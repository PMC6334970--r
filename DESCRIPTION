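Package: drumcall
Title: Feature-Based Detection and Quantification of Sciaenid Fish Calls
    in Estuarine Soundscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for passive acoustic monitoring of soniferous fishes of
    the family Sciaenidae (black drum, silver perch, spotted seatrout, red
    drum). Converts hydrophone WAV recordings to calibrated sound pressure
    levels, reorganizes signals into frame-matrix spectrograms with
    user-chosen time and frequency resolution, matches species-specific
    call templates ("3D features") by normalized centered correlation,
    counts calls per file, and evaluates detector output against manual
    annotations (identification rate, calling-intensity categories,
    nightly aggregation, Pearson correlation) together with environmental
    covariates (water temperature anomaly, lunar phase category, tidal
    range, day length). Includes a seeded synthetic-soundscape generator
    producing calibrated clips with ground-truth event manifests for
    detector calibration and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    zoo,
    withr,
    geosphere
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
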
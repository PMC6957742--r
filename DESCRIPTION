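Package: ichnoCT
Title: Ichnological Analysis of Sediment-Core CT Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
                  email = "author@example.org")
Description: Quantitative ichnology of unconsolidated marine sediment cores
    from X-ray computed tomography. Segments dense (e.g. pyritised) burrow
    fills in 3D core CT volumes with a marker-based watershed, separates and
    parameterises individual burrows (volume, length, equivalent diameter,
    z-orientation), derives downcore orientation profiles, Bioturbation
    Index logs on the 0-6 scale and horizontal/vertical interval
    classifications, combines them with 2D core-surface ichnology tables,
    and renders overlay figures. A ground-truthed synthetic half-core
    simulator supports validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ggplot2,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    grDevices,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
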
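Package: mitoshape
Title: Membrane Mechanics and Cristae Morphometrics of Mitochondrial Shape
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the sphere-to-tubule shape transition of individual
    mitochondria as a consequence of the surface-area difference between the
    outer membrane and the inner boundary membrane, created when inner
    membrane folds into cristae. Provides an axisymmetric Helfrich
    bending-energy minimizer under fixed mid-surface area and fixed
    normalized area difference (bilayer-couple-type constraints), 2D and
    inferred-3D morphometrics of traced mitochondria (circularity,
    cristae-to-inner-membrane fraction), a synthetic tracing generator that
    emulates manual tracings of live-cell STED images, and the cohort
    statistics used to relate cristae extent to organelle shape
    (Pearson correlation, median size splits, two-group comparisons,
    time-resolved profiles).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
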
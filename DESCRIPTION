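Package: plaquefractal
Title: Box-Counting Fractal Dimension of Atherosclerotic Plaque Borders
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the irregularity of atherosclerotic plaque borders on
    B-mode ultrasound long-axis views by fractal analysis. Images are
    binarized with an iterative-intermeans (IsoData) automatic threshold, the
    plaque border is extracted as the locus of highest Sobel gradient
    magnitude, and the fractal dimension of the border is estimated by box
    counting with multi-offset grids and log-log regression. Per-patient
    main-plaque and global fractal dimensions are aggregated from segment
    tables, and the reliability statistics used to validate the measurement
    (two-way random-effects intraclass correlation, Bland-Altman limits of
    agreement, repeatability coefficient, within-subject coefficient of
    variation, Spearman rank correlation) are provided. Synthetic generators
    for curves of known fractal dimension (straight lines, Koch curves,
    fractional Brownian motion graphs) and speckled two-region plaque-like
    images allow every pipeline stage to be validated without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    png,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'io.R'
    'segment.R'
    'boxcount.R'
    'synth.R'
    'cohort.R'
    'agreement.R'
    'pipeline.R'
    'plaquefractal-package.R'
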
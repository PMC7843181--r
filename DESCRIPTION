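Package: mcea
Title: Multiblock Confidence Ellipse Analysis for Weak Cross-Block
    Correlation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies weak correlation between blocks of variables
    measured on the same samples (for example climate, altitude and leaf
    chemistry of a crop recorded at many locations).  Each block is
    reduced by principal component analysis, per-class Gaussian
    confidence ellipsoids are fitted in score space, and an asymmetric
    class-by-class similarity index is formed from the counts of samples
    falling in overlapping ellipse regions.  Correlating two blocks'
    similarity profiles class by class yields an integrated measure of
    cross-block association that remains informative where ordinary
    regression explains almost none of the variance.  Includes the
    accompanying preprocessing chain (missing-value deletion, box-plot
    outlier removal, z-score normalization), forward-stepwise, partial
    least squares and support vector regression baselines under
    leave-one-out validation, and a synthetic multi-block generator with
    tunable cross-block coupling of class means.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    yaml,
    jsonlite,
    e1071,
    mixOmics,
    ggplot2,
    patchwork
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
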
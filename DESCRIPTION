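Package: scmeio
Title: Synaptonemal Complex Morphometry, QTL Mapping, and Mediation
    Analysis for Mouse Intercrosses
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the genetic analysis of synaptonemal complex (SC)
    length variation in F2 intercrosses. Measures total SC length from
    immunofluorescent spermatocyte spreads by a morphological
    gradient/Otsu/skeletonization pipeline, aggregates cell-level
    measurements into per-individual traits (mean SC length, MLH1 crossover
    count, SC-to-crossover ratio), performs weighted Haley-Knott regression
    genome scans with permutation-based genome-wide thresholds, 1.5-LOD
    support intervals and multiple-QTL variance decomposition, and carries
    out Sobel-test causal mediation analysis of pleiotropic loci with
    permutation null distributions and measurement-error sensitivity
    analysis. Includes a synthetic-data generator (images with known axis
    arc lengths; simulated intercross genotypes and bivariate cell-level
    phenotypes with mediation chains) so the full pipeline is testable
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    ggplot2,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
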
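Package: cbcnv
Title: Cluster-Based Copy Number Variation Detection from Tumor-Normal
    Read Depth Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects copy number variations (CNVs) from binned read-depth
    profiles of tumor-normal matched whole-genome sequencing samples. The
    pipeline bins read counts, masks ambiguous (N) regions, corrects GC
    content bias, denoises the depth profile with an exact one-dimensional
    fused-lasso (total-variation) fit, embeds each depth segment as a
    two-dimensional point (copy number estimate, neighborhood ratio
    deviation), assigns each segment a cluster-based abnormal score from a
    k-means partition split into large and small clusters, and calls CNVs
    with Tukey's fences on the score profile, typing them gain/loss and
    somatic/germline. Includes a tumor purity and coverage aware read-depth
    simulator with BED truth output and an evaluation harness (50%-overlap
    matching, sensitivity, FDR, precision/recall/F1, overlapping density
    score).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    GenomicRanges,
    IRanges,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
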
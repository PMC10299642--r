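Package: kinoprofile
Title: Quantifying Protein Regionalization Along Hair-Cell Kinocilia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the proximal-distal distribution of
    fluorescently tagged proteins along the kinocilium of sensory hair
    cells from confocal Z-stacks. Provides a ground-truthed synthetic
    scene generator (filament emitters convolved with an anisotropic
    Gaussian point-spread function), a seeded minimum-cost-path filament
    tracer with chord and arc length morphometry, fixed-step intensity
    line profiles with distal-tip registration, min-max/log2 presentation
    and Loess smoothing, per-larva top-five length aggregation with
    Welch/ANOVA/Tukey group statistics, and genomic-interval candidacy
    mapping of genes against marker-defined deafness critical regions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    BiocGenerics,
    GenomeInfoDb,
    graphics,
    jsonlite,
    pracma,
    Rcpp,
    rtracklayer,
    stats,
    tiff,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
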
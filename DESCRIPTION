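Package: bonlac
Title: Analysis of BONCAT-SILAC (BONLAC) De Novo Proteome Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of pulsed BONCAT-SILAC
    ("BONLAC") de novo proteome experiments. Reads MaxQuant-style
    proteinGroups tables, filters artifact rows, and orients normalized
    heavy/medium ratios into a consistent affected-vs-control fold-change
    matrix under per-replicate label swaps. Implements a
    coincidence-detection candidate screen (majority detection, average
    fold-change threshold, direction-consistency rules), cross-cohort
    concordance classification of candidate sets, average-linkage
    hierarchical clustering of mean-normalized log fold changes with
    Newick export, and the validation statistics used for western-blot
    follow-up (total-protein lane normalization, pooled-variance t tests,
    ordinary least-squares regression). A synthetic-data generator with
    known ground truth, including missing-not-at-random ratio dropout,
    supports calibration and end-to-end testing without raw
    mass-spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
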
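Package: barcodeval
Title: Evaluation of DNA Barcode Markers for Species Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for evaluating candidate DNA barcode markers
    (such as ITS2, ITS, rbcL, matK and psbA-trnH) for species discrimination.
    Provides quality filtering of taxonomy-annotated sequence sets, Kimura
    2-parameter genetic distances from pairwise or pre-computed alignments, six
    inter-/intra-specific divergence metrics (barcoding-gap analysis), Wilcoxon
    signed-rank comparison of markers, best-hit (BLAST1-style) and
    nearest-distance species identification with species- and genus-level
    success rates, traffic-light marker combination, a profile-HMM contaminant
    screen, and a Kimura 2-parameter sequence simulator that generates
    taxonomically structured datasets with known truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
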
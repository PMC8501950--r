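Package: qibcr
Title: Quantitative Image-Based Cytometry and Degenerate DNA Motif Scanning
Version: 0.1.0
Authors@R:
    person("QIBC", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Tools for quantitative image-based cytometry (QIBC): nuclei
    segmentation in DAPI images by two-class Otsu thresholding and seeded
    watershed, per-nucleus multi-channel intensity measurement, cell-cycle
    gating on integrated DAPI content, equal-depth subsampling across
    conditions, and the two standard QIBC figure types (DNA-content scatter
    coloured by a damage marker, and jittered dot-bar plots). Also counts
    non-overlapping occurrences of degenerate DNA motifs (e.g. TNTC) in
    sequences and FASTA genomes and reports occurrence density. A synthetic
    data module generates ground-truth nuclei scenes, renders multi-channel
    fields with noise, and produces DNA sequences with planted motifs so the
    whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    Biostrings,
    stats,
    graphics,
    grDevices,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
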
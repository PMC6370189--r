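Package: trmsig
Title: Differential Expression, Signature Overlap and Gene Set Enrichment
    for TGF-beta Imprinting of the Tissue-Resident Memory T Cell
    Transcriptome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for bulk RNA-seq FPKM matrices from a
    four-condition (untreated, TGF-beta, IL-2, IL-2/TGF-beta) in vitro
    CD8+ T-cell stimulation design. Provides expression filtering and
    transformation, PCA and Ward/Chebyshev hierarchical clustering,
    moderated-t differential expression with Benjamini-Hochberg FDR
    control and fold-change tier tables, directional concordance testing
    of a differential-expression result against a directional gene
    signature with a with-replacement bootstrap enrichment P-value, and a
    from-scratch gene set enrichment analysis (Signal2Noise ranking,
    weighted running-sum enrichment score, permutation null, NES and
    FDR q-values). A synthetic expression generator with a machine-readable
    planted truth emulates the 12-sample study design for calibration and
    parameter-recovery testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea,
    optparse
Config/testthat/edition: 3
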
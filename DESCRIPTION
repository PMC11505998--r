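Package: oncoresponse
Title: Preclinical Drug-Response and Tumor-Progression Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for the quantitative analysis of preclinical
    oncology drug-response studies. Implements growth-rate-normalized (GR)
    dose-response metrics (GR50, GRmax, GRaoc, absolute IC50) with sigmoidal
    curve fitting, Chou-Talalay median-effect synergy analysis (combination
    index), flow-cytometry readout summarization (live gating, MFI
    normalization, EdU-positive fractions), qPCR delta-delta-Ct relative
    expression with dual reference genes, xenograft tumor-growth-inhibition
    (TGI) analysis with welfare monitoring, and a transcriptomic
    tumor-progression trajectory (batch diagnostics and correction, top-IQR
    PCA, grade-seeded MST plus principal-curve pseudotime, resampled
    pseudotime-gene correlation with FDR control, preranked permutation GSEA,
    and two-group survival analysis). Every stage has a paired synthetic-data
    generator with known ground truth so the whole pipeline is testable
    end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    mclust,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    fgsea,
    DESeq2,
    igraph
Config/testthat/edition: 3
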
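Package: meningiomics
Title: Integrated Genomic, Transcriptomic and Epigenomic Analysis of
    Atypical Meningioma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for separating primary atypical from
    benign meningiomas across assays: somatic variant filter cascades and
    clonality (cancer-cell-fraction) estimation, B-allele-frequency-based
    tumour purity and copy-number event classification with
    percentage-of-genome-altered scoring, moderated differential expression
    and a random-forest grade classifier, miRNA-mRNA anti-correlation
    regulatory networks, consensus clustering of DNA methylation with
    regulatory-domain gene-set enrichment, and super-enhancer
    identification with expression concordance. Includes a seeded
    synthetic-cohort generator with planted ground truth so the whole
    pipeline can be exercised end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    limma,
    randomForest,
    mclust,
    S4Vectors,
    IRanges,
    GenomicRanges,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    cluster
Config/testthat/edition: 3
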
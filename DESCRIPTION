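Package: cfscreen
Title: Cell-Free DNA Prenatal Screening: Simulation, Calling and Concordance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Extended non-invasive prenatal testing (NIPT-PLUS) computations
    from binned maternal-plasma cell-free DNA read counts: equal-read genome
    windowing with least-squares GC correction, per-chromosome Z-score
    aneuploidy and sex-chromosome karyotype calling against a euploid
    reference panel, least-squares changepoint segmentation with a dynamic
    threshold for sub-chromosomal copy-number variants with fetal/maternal
    origin attribution, and dual fetal-fraction estimation (chrY-based and
    short-fragment seqFF-style regression) with a lower detection limit.
    Includes a synthetic maternal-plasma cohort generator with placental and
    fetal compartments (confined placental mosaicism, fetal mosaicism), an
    ISCN-style microarray result parser, and screening-versus-diagnostic
    concordance metrics (sensitivity, PPV, miss rate, Wilson confidence
    intervals) with packaged count fixtures.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
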
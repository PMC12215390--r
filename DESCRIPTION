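Package: tlabelbench
Title: Simulation and Quantification Toolkit for Metabolic-Labeling
    Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for benchmarking 4-thiouridine (4sU) metabolic-labeling
    single-cell RNA-seq chemistries and platforms without sequencing data.
    Includes a synthetic-data generator with known ground truth (per-gene
    fraction of newly synthesized RNA, conversion rates, germline SNPs),
    per-UMI consensus calling and substitution-rate quantification with
    Phred-quality and SNP filtering, a two-component binomial mixture EM
    estimator separating new from pre-existing RNA, maternal/zygotic gene
    classification from new-to-total RNA ratios, RNA half-life estimation
    from labeled fractions, and depth-normalized library-complexity
    prediction with LOESS and linear fits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    graphics,
    methods,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
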
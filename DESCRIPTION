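Package: trdprs
Title: Polygenic Scores of Treatment Response and Treatment-Resistant Depression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Register-based phenotyping of treatment-resistant depression (TRD)
    from prescription and electroconvulsive-therapy (ECT) records, genotype and
    sample quality control, polygenic risk score (PRS) construction from
    LD-rescaled GWAS summary statistics, and the full TRD vs non-TRD
    association battery (Welch t-tests, PC-adjusted logistic regression,
    Nagelkerke and liability-scale variance explained, quartile trend tests,
    Benjamini-Hochberg FDR over the primary tests). Includes a synthetic-study
    generator emulating the register and genetic structure of a Swedish
    MDD case sample, so the whole pipeline runs end-to-end without any
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    optparse
Config/testthat/edition: 3
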
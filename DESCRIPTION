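Package: protmr
Title: Proteome-Wide Two-Sample Mendelian Randomization with cis-pQTL
    Instruments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for proteome-wide two-sample Mendelian randomization
    from GWAS summary statistics: cis-pQTL instrument selection
    (genome-wide significance, MHC exclusion, cis-window filtering, LD
    clumping, F-statistic screening), exposure-outcome harmonization
    including palindromic-variant resolution, a full estimator and
    sensitivity suite (Wald ratio, fixed- and multiplicative
    random-effects IVW, Cochran's Q, MR-Egger with intercept test,
    weighted median, weighted mode, MR-PRESSO), FDR-controlled
    proteome screening and phenome-wide (PheWAS) screening, and a
    seeded synthetic summary-statistics generator with known ground
    truth for end-to-end validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    metafor
Config/testthat/edition: 3
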
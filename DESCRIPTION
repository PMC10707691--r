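Package: hrdgia
Title: Genomic Instability Assessment and HRD Classification from Shallow
    Whole-Genome Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Scores homologous recombination deficiency (HRD) from shallow
    whole-genome sequencing (0.4-0.8x) read counts. Bins are normalized to
    log2 copy ratios with GC correction, segmented per chromosome arm by an
    exact penalized least-squares change-point search, and large-scale
    genomic alterations (LGAs; breakpoints flanked by >= 10 Mb segments) are
    counted across several window-size models and integrated into a genomic
    instability assessment (GIA) score. Includes three-class and two-class
    HRD calling, Myriad-style reference-score banding, method-concordance
    statistics (Cohen's kappa, percent positive agreement, Spearman
    correlation, Fisher's exact test), Kaplan-Meier / log-rank / Cox survival
    analysis by HRD class, and a seeded simulator of FFPE tumor sWGS bin
    counts and clinical cohorts so the entire pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    survival,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
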
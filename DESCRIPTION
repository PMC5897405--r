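Package: mitohet
Title: Mitochondrial Homopolymer Heteroplasmy, Copy Number and Lifespan
    Cohort Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies mitochondrial DNA repeat-length heteroplasmy at
    anchored homopolymer loci -- such as the poly-A loop of the origin of
    light-strand replication (OriL) -- from aligned deep-sequencing reads by
    CIGAR-based window reconstruction, with the read- and motif-level
    quality filters used in mtDNA amplicon resequencing. Quantifies
    mtDNA/nuclear-DNA copy-number ratios from droplet digital PCR counts by
    Poisson zero-class inversion with delta-method intervals. Provides the
    cohort statistics layer of lifespan studies (Kaplan-Meier curves with
    median confidence intervals, log-rank and Gehan-Breslow tests, Spearman
    rank correlation with exact small-sample p-values, Mann-Whitney U, and
    noncentral-t sample-size calculation), together with a seeded
    synthetic-data generator (reads with homopolymer slippage, droplet
    counts, lifespan cohorts) that supplies ground truth for
    parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
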
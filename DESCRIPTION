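Package: hrdgi
Title: Genomic Instability Scoring and Clinical Association from
    Segmented Tumor Copy-Number Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Turns segmented tumor copy-number and B-allele-frequency
    profiles from a targeted sequencing panel into a per-sample genomic
    instability (GI) parameter vector, a mutational homologous
    recombination deficiency (HRD) status, and a clinical association
    layer for early-phase trial cohorts.  Includes purity-aware
    copy-number event calling with significance and minimum-length
    artifact filters, loss-of-heterozygosity detection against a
    heterozygosity mask built from a small panel of normals, the
    24-parameter GI feature vector with median/quartile categorization,
    RECIST response groupings (ORR, CBR, long-term responders) with
    exact binomial confidence intervals, Kaplan-Meier and log-rank
    survival comparisons, a rank-sum/Cohen's-d association scan, and a
    synthetic-cohort generator with known ground truth for validating
    the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
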
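Package: grapeAncestry
Title: PCA-Projection Ancestry Estimation for Interspecific Grape Hybrids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates the Vitis vinifera fraction of interspecific grape
    hybrids from biallelic genotype calls. Implements the full analysis chain:
    curation of a samples-by-sites dosage matrix (depth masking, missingness,
    minor-allele-frequency and exact heterozygote-excess Hardy-Weinberg
    filters), identity-by-state relatedness screening, LD-kNNi genotype
    imputation, windowed r-squared linkage-disequilibrium pruning, principal
    component analysis fitted on equal-sized wild Vitis and V. vinifera
    ancestral panels with projection of hybrid samples, and the PC1
    distance-ratio ancestry coefficient. In-silico F1 and backcross cohort
    simulation validates the estimator, and a synthetic-data generator with
    known ancestry truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
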
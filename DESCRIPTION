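Package: divscan
Title: Runs of Homozygosity, Inbreeding Coefficients, F_ST Selection
    Scans and LD-Based Effective Population Size for SNP-Array Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying genetic diversity and selection history
    in livestock SNP-array cohorts. Detects runs of homozygosity (ROH) with
    a sliding-window genotype scan, summarises ROH by physical length class
    and genetic (cM) length for demographic inference, and calls ROH
    hotspots. Computes four inbreeding coefficients per animal (F_ROH at
    1/5/10 Mb thresholds, pedigree F via the Meuwissen-Luo algorithm,
    VanRaden genomic-relationship F, and excess-homozygosity F) together
    with their correlations on pedigree-depth-restricted subsets. Scans for
    selection signatures with per-SNP Weir-Cockerham F_ST, five-SNP window
    averaging and empirical-percentile region calling, and estimates
    historical effective population size from distance-binned,
    sample-size-adjusted linkage disequilibrium. Includes synthetic-cohort
    generators (Balding-Nichols divergence, pedigree gene dropping with
    identity-by-descent ground truth, forward Wright-Fisher simulation)
    so every stage is testable against known truth, plus PLINK PED/MAP and
    BED/BIM/FAM readers and writers and a configurable end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
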
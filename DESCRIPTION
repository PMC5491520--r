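Package: rvtiers
Title: Rare-Variant Candidate-Gene Burden and SKAT-O Analysis with Tiered
    Gene Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for rare-variant candidate-gene
    case-control studies. Implements an allele-frequency rarity and novelty
    filtering cascade against multiple internal and external reference
    panels, consequence-based functional stratification with per-predictor
    deleteriousness strata, clinical-variant triage against ClinVar labels,
    a sample quality-control cascade (contamination, depth, concordance,
    missingness, ancestry, sequential relatedness pruning), gene- and
    tier-level weighted burden and SKAT-O association tests with
    mixture-of-chi-square p-values and adjusted odds ratios, single-variant
    contingency statistics, and a simulation-based power analysis for the
    burden test under a MAF-dependent log-odds effect model. A synthetic
    cohort generator produces haplotype pools, case-control genotypes,
    reference-panel frequencies, variant annotations and planted
    quality-control failures so the whole pipeline is testable end to end
    without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
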
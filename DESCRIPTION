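Package: dnec
Title: Definitive Necrotizing Enterocolitis Scoring and Colonic Microbiome
    Analysis for Preterm Piglet Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements the Definitive-NEC (D-NEC) composite diagnosis for
    preterm piglet models of necrotizing enterocolitis: clinical sickness
    scoring, gross and histologic injury grading aggregated over intestinal
    segments, quantification of bacterial translocation as colony-forming
    units per gram of organ tissue, and the 3-of-4 composite call. Provides
    the accompanying cohort statistics (exact tie-corrected Mann-Whitney U
    test, Kruskal-Wallis, log-rank survival contrast, 2^-ddCt relative
    expression) and a downstream 16S microbiome workflow starting from a
    denoised feature table (rarefaction, prevalence filtering, taxonomy
    collapse, alpha diversity, weighted UniFrac, principal coordinates,
    PERMANOVA, per-taxon abundance contrasts). Includes seed-deterministic
    synthetic cohort and Dirichlet-multinomial microbiome generators so the
    whole pipeline is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    ape,
    survival
Suggests:
    testthat (>= 3.0.0),
    optparse,
    vegan,
    phyloseq,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
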
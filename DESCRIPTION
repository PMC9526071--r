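Package: wolbscan
Title: Endosymbiont Detection and Strain Networks from Host Resequencing Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects Wolbachia infection in host insects from summaries of
    endosymbiont-mapped resequencing reads, calibrates read-count detection
    thresholds against PCR gold-standard labels, calls haploid Wolbachia
    haplotypes from per-site allele depths, groups haplotypes into strains by
    95% statistical-parsimony networks, ordinates haplotypes by principal
    coordinates analysis of uncorrected p-distances, and tabulates infection
    prevalence and strain distributions across localities and host lineages.
    Includes a seeded synthetic-data generator that emulates the statistical
    structure of genotyping-by-sequencing surveys so the full pipeline can be
    exercised without raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    data.table,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
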
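Package: nmdburden
Title: Population Burden of Pathogenic Loss-of-Function Variants and
    Allele-Frequency Thresholds
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for measuring the population burden of pathogenic
    variants in large sequencing cohorts and deriving empirical
    allele-frequency thresholds for clinical variant interpretation.
    Classifies truncating variants as triggering or escaping
    nonsense-mediated decay (NMD) from transcript structure (the 50-bp
    rule, final-intron splice sites, and experimental-escape overrides),
    computes depth- and quality-filtered cohort allele frequencies,
    aggregates per-submitter assertions into consensus pathogenicity
    calls, bins frequencies per gene, flags recurrent founder-mutation
    candidates, and compares frequency distributions with rank-sum
    tests. A synthetic-data generator emits genomes, transcript models,
    cohort VCFs, submission tables and publication counts with a
    ground-truth manifest so every stage is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    rtracklayer,
    seqinr,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
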
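Package: alujump
Title: Massively Parallel Jumping Assay Analysis for Alu Retrotransposons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for massively parallel jumping assays (MPJA)
    of Alu retrotransposition. Reconstructs mutant haplotypes from SAM
    alignment records (CIGAR/MD/NM tags), counts haplotype abundance in
    plasmid and post-retrotransposition ("jumping") libraries, tests
    differential activity with a negative-binomial Wald model, classifies
    high/low/non-jumpers, estimates per-variant and 5-bp sliding-window
    activity effects by replicate-conditional linear regression, tests
    hypergeometric enrichment of jumper variants in SRP9/14 binding
    regions, and compares jumping haplotypes to genomic AluS sequences by
    edit distance. Includes a seeded synthetic-data generator emulating
    error-prone PCR libraries and activity-dependent selection so every
    stage is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
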
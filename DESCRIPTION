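Package: mutacc
Title: Mutation-Accumulation Rate Calculus, Spectra, Context G-Tests and
    Bottleneck Selection Simulation
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for contrasting microbial mutation-rate estimates from
    mutation-accumulation (MA) and specific-locus experiments. Provides
    exact rate arithmetic (per-site and per-genome rates, expected
    substitution-class counts, fold contrasts), strand-collapsed mutation
    spectrum classification, synonymous-status and codon-usage-vector
    assignment for observed substitutions, a replicated goodness-of-fit
    G decomposition (pooled, heterogeneity and total components) for
    flanking-base G/C composition around mutated sites, exact two-tailed
    binomial composition tests, and a serial-bottleneck population
    simulator for estimating selection coefficients consistent with an
    observed depression of the MA rate. A synthetic-data module generates
    genomes, usage-biased coding genes, context-weighted mutation tables
    and Poisson MA counts with known parameters so every stage is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    withr
biocViews: Genetics, Software, StatisticalMethod, SomaticMutation
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
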
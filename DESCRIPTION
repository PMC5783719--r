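Package: htrec
Title: Structural Variant Simulation, Classification and Balancer-Based
    Scoring of Heterologous Recombination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the genomic consequences of heterologous
    recombination (Ht-REC). One half of the package builds derivative
    chromosomes by applying rearrangement events (deletions, tandem
    duplications, inversions, templated duplications with distant
    intra-chromosomal insertion, breakage-fusion-bridge cycles,
    chromothripsis), derives the breakpoint-junction and copy-number
    observables a whole-genome-sequencing pipeline would report, and
    classifies such observables back into event classes, with cohort-level
    rank-based comparisons. The other half implements a marker-exchange
    scoring system for recombination across a balancer inversion in
    Caenorhabditis elegans: a segregation model with per-genotype
    viabilities, progeny simulation, recombinant-frequency estimation with
    exact confidence intervals, frequency comparisons, fold changes, and
    two-marker genetic map distances.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    IRanges,
    S4Vectors,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
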
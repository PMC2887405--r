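Package: srnapop
Title: Population Genetics of Small RNA Loci in Domesticated Rice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for surveying sequence variation and selection at
    plant small-RNA loci (MIRNA, TAS3 ta-siRNA and miRNA-like long-hairpin
    genes) from per-locus multiple sequence alignments of resequencing
    panels. Computes nucleotide diversity (Watterson's theta and pairwise
    pi) per locus, per annotated region (mature miRNA, precursor, flanks)
    and per population; Tajima's D with coalescent fixed-S significance;
    multi-locus Hudson-Kreitman-Aguade (HKA) tests against neutral
    reference loci and an outgroup; fold-reduction screening of cultivated
    versus wild diversity; and classification of putative
    domestication-selection candidates. Includes a coalescent simulator
    with bottleneck demography that generates complete synthetic
    indica/japonica/wild/outgroup panels for testing every pipeline stage,
    a functional-region mutation catalogue with per-population allele
    frequencies, and a penalty-scored miRNA target-site scanner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
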
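Package: slocusmod
Title: Discovery of Small-RNA Dominance Modifiers at the Brassicaceae S-Locus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for identifying candidate small-RNA-based
    dominance modifiers at the self-incompatibility (S) locus of Brassicaceae,
    built around the allotetraploid Capsella bursa-pastoris system. Detects
    inverted repeats with an einverted-style banded local alignment, screens
    them as hairpin precursor candidates with structural filter rules, maps
    and quantifies 18-27 nt small-RNA reads, scores sRNA-target affinity with
    a G:U-wobble-aware Smith-Waterman scheme, estimates nucleotide diversity
    and Watterson's theta from coding alignments, calls frameshift
    pseudogenization of SCR, classifies S-haplotype presence from read-depth
    profiles, and generates seeded synthetic data with planted features so
    the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    BiocGenerics,
    Biostrings,
    methods,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
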
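Package: parcomp
Title: Comparative Analysis of Pseudoautosomal and Homologous Autosomal Regions
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to compare an annotated pseudoautosomal (PAR) genomic
    region against its homologous autosomal region in a related species:
    gene-structure and collinearity comparison, GC and third-codon-position
    (GC3) composition with two-sample tests, intergenic expansion statistics,
    perfect tandem-repeat (microsatellite) detection with long-mer filtering,
    LTR retrotransposon insertion dating from paired-LTR divergence, and
    two-point genetic linkage analysis for pseudo-backcross designs with
    Kosambi and Haldane map functions. Includes a seeded synthetic-data
    generator that emulates a homologous region pair and a segregation
    matrix, so every pipeline stage can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
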
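Package: satmethyl
Title: Satellite DNA Monomer Diversity and Bisulfite Methylation Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Characterization of tandemly repeated satellite DNA monomer
    families and their cytosine methylation from cloned-sequence data.
    Provides monomer alignment handling and majority-rule consensus
    derivation, DnaSP-style nucleotide diversity (overall and sliding
    window) with mean +/- 2SD conserved/variable segment classification,
    bisulfite methylation calling with a mutation-bias normalization and
    CG/CHG/CHH context partitioning, bisulfite conversion-efficiency
    estimation, Spearman correlation of methylation and diversity tracks,
    in-silico methylation-sensitive restriction digestion of tandem arrays
    with multimer-ladder summaries, and a fully seeded synthetic-data
    generator for satellite families, methylation states and bisulfite
    clone sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
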
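Package: noiascan
Title: Genotype-Phenotype Discovery with Orthogonal Genetic-Effects Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Small-cohort genotype-phenotype discovery tools: multi-caller
    consensus and homozygous-discordance variant filtering with functional
    annotation gating, case/control and quantitative-trait association with
    an adaptive permutation engine, NOIA orthogonal genetic-effects models
    for up to three biallelic loci with model-space screening, composite
    metabolic trait derivation and classification, conserved-window capture
    probe design with k-mer frequency filtering, and a synthetic cohort
    generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    vcfR,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
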
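Package: autozygmap
Title: Autozygosity Mapping and Recessive Variant Prioritization in Closed Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale re-usable pipeline for mapping monogenic autosomal
    recessive traits in closed (breed-like) populations: SNP-array quality
    control, kinship-corrected mixed-model association with inflation
    diagnostics, shared-homozygous-segment (autozygosity) mapping with
    critical-interval definition, a private-variant prioritization cascade
    against a control genome panel, minimal transcript-aware consequence
    annotation with HGVS c./p. output, and exact genotype-phenotype
    association tests. Includes a gene-drop simulator of a bottlenecked
    random-mating population carrying a recessive causal variant on a shared
    identical-by-descent haplotype, used for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    vcfR,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    Matrix,
    optparse
Config/testthat/edition: 3
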
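Package: clonalloh
Title: Mutation Classification and Copy-Neutral Loss of Heterozygosity in Clonal Lineages
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for genomic inference in clonal (automictically parthenogenetic)
    lineages. Reads multi-sample VCFs into genotype matrices, applies depth and
    missingness hard filters, identifies sites that distinguish a focal clonal
    sub-lineage from its wild-type relatives, and classifies them into de novo
    point mutations, short gene-conversion tracts, and large segmental
    copy-neutral loss-of-heterozygosity (LOH) events. Includes windowed
    relative-heterozygosity and normalized-depth scans, per-chromosome
    sequence-feature profiling for supergene diagnosis, IUPAC-coded alignment
    export for diploid-aware phylogenetics, generation-number estimation from
    de novo mutation counts, morphometric and raiding-assay summaries, and a
    forward simulator of clonal diploid genome evolution under central-fusion
    automixis that emits VCFs together with a machine-readable truth ledger for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    IRanges,
    GenomicRanges,
    S4Vectors,
    BiocGenerics,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
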
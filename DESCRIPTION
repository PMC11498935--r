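Package: somatree
Title: Somatic Mutation Landscapes on Physical Tree Architectures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying somatic single-nucleotide variants (SNVs)
    accumulating along the physical architecture of long-lived trees:
    replicate-concordance SNV discovery with GATK-style hard filters,
    mutation-rate estimation per meter of growth and per year
    (zero-intercept regression with diploid callable-site scaling),
    neighbor-joining reconstruction and Robinson-Foulds congruence with
    the physical branching structure, 96-trinucleotide-context mutational
    spectra with CpG enrichment and signature cosine similarity, a
    codon-opportunity test of selection on somatic and inter-individual
    variants, and a replication-dependent/independent mutagenesis model.
    A seeded synthetic-data generator produces annotated genomes, branch
    architectures, somatic mutations and noisy replicate call tables so
    every stage of the analysis is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    vcfR,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
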
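Package: majref
Title: Population Major-Allele Reference Genome Construction and Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds population-specific major-allele reference genomes from
    joint cohort VCFs. Computes cohort alternate allele frequencies,
    identifies sites where the majority allele differs from the reference
    (alternate allele frequency above 50 percent), substitutes those alleles
    into a reference FASTA with exact coordinate liftover (UCSC chain
    output), and quantifies the resulting per-sample variant-call reduction
    by reprojecting callsets between references. Also provides the
    supporting population-genetic toolkit: allele-frequency spectrum
    binning, identity-by-state distances with neighbor-joining tree based
    representative sample selection, per-sample heterozygosity and
    inbreeding statistics, population-specific variant filters, catalog
    overlap, and a fully seeded synthetic diploid cohort generator for
    offline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    parallel,
    Biostrings,
    vcfR,
    ape
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    GenomicRanges,
    IRanges,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
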
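Package: toposeqr
Title: Mapping Topoisomerase Cleavage Sites from Strand-Specific Fragment Ends
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for locating type-IIA topoisomerase cleavage sites at
    single-nucleotide resolution from sequencing of drug-trapped covalent
    cleavage complexes. Aligned fragments are converted into strand-specific
    per-position counts of fragment 3'- and 5'-ends (N3E/N5E) and coverage;
    paired strand-specific N3E spikes flanking the 4-bp gap left by the
    staggered double-strand break are called as cleavage sites with an
    Audic-Claverie count test, reconciled across replicates, and classified
    as canonical or composite and primary or satellite. Downstream analyses
    derive the cleavage motif (position frequency matrix, information
    content, dyad symmetry, long-range GC profile) and whole-genome
    statistics (binomial region enrichment, binned densities, metagene
    profiles over transcription units, downstream correlations). A simulator
    of trapped cleavage complexes with the exact staggered-cut geometry
    generates fully synthetic genomes, fragment sets and truth tables so the
    whole pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    methods,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
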
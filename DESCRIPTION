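Package: aubscan
Title: Detection of Chromosomal Micro-Mosaicism from A-U-B Chimeric Sequencing Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects sporadic chromosomal chimeras (micro-mosaicism) in DNA
    sequencing reads. Reads are split into fixed-size bins that are aligned
    independently; reads whose bins align uniquely to two non-homologous
    chromosomes with a single unaligned transition bin (A-U-B reads) are
    called as chimeric events, refined to single-base junction resolution
    with a sliding-window alignment, and classified as dually aligning
    (microhomology), base-to-base or gapped from the signed junction gap.
    Interallelic (homologous-chromosome) chimeras are detected from trio
    genotypes by parent-of-origin read phasing with a single-switch rule and
    a somatic-mutation-rate correction. A seeded simulator generates toy
    genomes with planted repeat families, reads with implanted junctions of
    the three classes, and trios with allelic switches, so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    vcfR,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
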
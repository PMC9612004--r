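Package: intronsig
Title: Intronization Signatures in Coding Exons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide analysis of cryptic splice signals in coding exons,
    built around the ciliate Paramecium tetraurelia. Enumerates all
    GT|AG-bounded segments of the coding exome, quantifies purifying
    selection against candidate cryptic introns through a DNA strand
    asymmetry (DSA) score with a gene-level bootstrap, quantifies splicing,
    intron retention and alternative splice-site usage from splice-junction
    tables, scans introns for premature termination codons under the ciliate
    nuclear genetic code (translation table 6), and stratifies all signals
    by exon position and gene expression. A synthetic-data module generates
    genomes, annotations and junction tables with known planted signal so
    every stage has a parameter-recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
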
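Package: asmqc
Title: Pre- and Post-Assembly Sequencing Quality Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-way quality assessment of de novo genome assemblies and their
    input reads. The pre-assembly module samples reads from FASTQ, computes
    per-read base-quality statistics (MinimalQ, the %HighQ(q) profile) and
    categorizes reads into high-, medium- and poor-quality groups. The
    post-assembly module digests SAM alignments of the sampled reads against
    the assembled scaffolds, assigns each read one of seven mapping labels
    (P/S/C/O/M/F/N), derives mismatch, clip and N-density ratios, and computes
    the poorly-mapped percentage (PM%) averaged over two alignment strategies.
    Assembly contiguity metrics (N25/N50/N75, L80/L90/L99, GC%, Ns per 100
    kbp) are computed natively. Results are emitted as JSON bundles and
    self-contained HTML reports; a synthetic-fixture generator produces reads
    and SAM records with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    BiocGenerics,
    Biostrings,
    ShortRead,
    Rsamtools,
    GenomicAlignments,
    S4Vectors,
    IRanges,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
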
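Package: qsquant
Title: Quality-Score Quantization for Nanopore FASTQ Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Lossy quantization of Phred quality scores in nanopore FASTQ
    files. Provides interval quantizers (including the two-, four- and
    eight-level schemes used to study the effect of quality-score
    information loss on assembly polishing and variant calling), constant
    quantizers, and a repeat-context-dependent quantizer that keeps higher
    score resolution within and near homopolymers and dinucleotide repeats.
    Includes a streaming 4-line FASTQ reader/writer with gzip transparency,
    seeded exact-count read downsampling, variant-calling metric arithmetic
    (recall, precision, F1), compression-ratio and space-saving reports, a
    zeroth-order empirical-entropy diagnostic, a seeded generator of
    nanopore-like reads with planted repeats and exhaustive ground truth,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'qsquant-package.R'
    'AllGenerics.R'
    'quantizers.R'
    'FastqReads.R'
    'fastq-io.R'
    'repeats.R'
    'simulate.R'
    'metrics.R'
    'compress.R'
    'cli.R'
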
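#' @include qsquant-package.R
NULL

#' Apply a quantizer to integer quality scores
#'
#' Maps each Phred score in `scores` through the quantizer `x`. All scores
#' must lie in the nanopore Phred+33 domain \[0, 93\].
#'
#' @param x A [ScoreQuantizer-class] object.
#' @param scores Integer vector of quality scores in \[0, 93\].
#' @return Integer vector of quantized scores, same length as `scores`.
#' @examples
#' quantizeScores(builtinQuantizer("Q4"), c(0, 8, 14, 20, 93))
#' @export
setGeneric("quantizeScores", function(x, scores) standardGeneric("quantizeScores"))

#' Full lookup table of a quantizer
#'
#' @param x A [ScoreQuantizer-class] object.
#' @return Integer vector of length 94: element `i` is the quantized value of
#'   score `i - 1`.
#' @examples
#' table(scoreMap(builtinQuantizer("Q8")))
#' @export
setGeneric("scoreMap", function(x) standardGeneric("scoreMap"))

#' Size of a quantizer's output alphabet
#'
#' @param x A [ScoreQuantizer-class] object.
#' @return Integer: the number of distinct output values.
#' @examples
#' alphabetSize(builtinQuantizer("Q2"))
#' @export
setGeneric("alphabetSize", function(x) standardGeneric("alphabetSize"))

#' Quantize the quality scores of a set of reads
#'
#' Rewrites the quality string of every read through the quantizer `x`;
#' headers, base sequences and separator lines are preserved verbatim.
#' For a [ContextQuantizer-class] the mapping of each score additionally
#' depends on the read position's proximity to repetitive sequence.
#'
#' @param x A [ScoreQuantizer-class] or [ContextQuantizer-class].
#' @param reads A [FastqReads-class] object.
#' @return A [FastqReads-class] object with quantized quality strings.
#' @examples
#' reads <- FastqReads("r1", "ACGT", "", list(c(0L, 7L, 8L, 93L)))
#' qualityScores(quantizeReads(builtinQuantizer("Q2"), reads))
#' @export
setGeneric("quantizeReads", function(x, reads) standardGeneric("quantizeReads"))
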
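#' @include quantizers.R
NULL

#' Container for 4-line FASTQ records
#'
#' Parallel character vectors holding, per read, the header (line 1 without
#' the leading `@`), the base sequence, the separator (line 3 without the
#' leading `+`, often empty) and the quality string in Phred+33 encoding
#' (ASCII 33 is score 0, ASCII 126 is score 93). Quality is kept encoded so
#' that reading and re-writing an untransformed file is byte-identical;
#' [qualityScores()] decodes on demand.
#'
#' @slot header Character vector.
#' @slot sequence Character vector; bases may be any case, `N` and IUPAC
#'   letters allowed.
#' @slot separator Character vector.
#' @slot quality Character vector, each string the same length as the
#'   corresponding sequence, characters restricted to ASCII 33--126.
#'
#' @seealso [FastqReads()], [readFastq()], [writeFastq()]
#' @name FastqReads-class
#' @exportClass FastqReads
setClass("FastqReads",
  representation(
    header = "character", sequence = "character",
    separator = "character", quality = "character"
  )
)

setValidity("FastqReads", function(object) {
  n <- length(object@header)
  if (length(object@sequence) != n || length(object@separator) != n ||
      length(object@quality) != n) {
    return("header, sequence, separator and quality must have equal length")
  }
  if (n == 0L) return(TRUE)
  if (anyNA(object@header) || anyNA(object@sequence) ||
      anyNA(object@separator) || anyNA(object@quality)) {
    return("fields must not contain NA")
  }
  bad <- which(nchar(object@sequence, type = "bytes") !=
                 nchar(object@quality, type = "bytes"))
  if (length(bad)) {
    return(sprintf(
      "record %d: sequence length %d != quality length %d",
      bad[1L], nchar(object@sequence[bad[1L]]), nchar(object@quality[bad[1L]])
    ))
  }
  bad <- which(grepl("[\r\n]", object@header) | grepl("[\r\n]", object@separator))
  if (length(bad)) {
    return(sprintf("record %d: header/separator contains a line break", bad[1L]))
  }
  bad <- which(grepl("[^\x21-\x7e]", object@quality, perl = TRUE, useBytes = TRUE))
  if (length(bad)) {
    qual <- object@quality[bad[1L]]
    codes <- utf8ToInt(qual)
    pos <- which(codes < 33L | codes > 126L)[1L]
    return(sprintf(
      "record %d: malformed quality character at position %d (ASCII %d outside [33, 126])",
      bad[1L], pos, codes[pos]
    ))
  }
  TRUE
})

#' Construct a FastqReads object
#'
#' @param header,sequence,separator Character vectors of equal length;
#'   `separator` defaults to empty strings.
#' @param quality Either a character vector of Phred+33 quality strings or a
#'   list of integer score vectors (encoded via [encodeQuality()]).
#' @return A [FastqReads-class] object.
#' @examples
#' FastqReads(
#'   header = "read1", sequence = "ACGT", separator = "",
#'   quality = list(c(10L, 20L, 30L, 40L))
#' )
#' @export
FastqReads <- function(header = character(), sequence = character(),
                       separator = rep("", length(header)), quality = character()) {
  if (is.list(quality)) {
    quality <- vapply(quality, encodeQuality, character(1))
  }
  new("FastqReads",
    header = as.character(header), sequence = as.character(sequence),
    separator = as.character(separator), quality = as.character(quality)
  )
}

#' @describeIn FastqReads-class Number of reads.
#' @param x A `FastqReads` object.
#' @export
setMethod("length", "FastqReads", function(x) length(x@header))

#' @describeIn FastqReads-class Subset reads (integer/logical indexing).
#' @param i Index vector.
#' @param j,...,drop Ignored.
#' @export
setMethod("[", "FastqReads", function(x, i, j, ..., drop = FALSE) {
  initialize(x,
    header = x@header[i], sequence = x@sequence[i],
    separator = x@separator[i], quality = x@quality[i]
  )
})

#' Combine FastqReads objects
#'
#' @param x,... `FastqReads` objects, concatenated in argument order.
#' @return A single [FastqReads-class] object.
#' @export
setMethod("c", "FastqReads", function(x, ...) {
  all <- c(list(x), list(...))
  new("FastqReads",
    header = unlist(lapply(all, slot, "header")),
    sequence = unlist(lapply(all, slot, "sequence")),
    separator = unlist(lapply(all, slot, "separator")),
    quality = unlist(lapply(all, slot, "quality"))
  )
})

setMethod("show", "FastqReads", function(object) {
  n <- length(object)
  cat(sprintf("FastqReads with %d read%s\n", n, if (n == 1L) "" else "s"))
  for (i in seq_len(min(n, 3L))) {
    s <- object@sequence[i]
    cat(sprintf(
      "  @%s  %d bp  %s%s\n", object@header[i], nchar(s),
      substr(s, 1L, 24L), if (nchar(s) > 24L) "..." else ""
    ))
  }
  if (n > 3L) cat(sprintf("  ... and %d more\n", n - 3L))
  invisible(object)
})

#' @describeIn FastqReads-class Read headers (without the leading `@`).
#' @export
readHeaders <- function(x) x@header

#' @describeIn FastqReads-class Base sequences.
#' @export
readSequences <- function(x) x@sequence

#' @describeIn FastqReads-class Separator lines (without the leading `+`).
#' @export
readSeparators <- function(x) x@separator

#' @describeIn FastqReads-class Phred+33-encoded quality strings.
#' @export
qualityStrings <- function(x) x@quality

#' @describeIn FastqReads-class List of integer score vectors, one per read.
#' @export
qualityScores <- function(x) lapply(x@quality, decodeQuality)

#' Decode a Phred+33 quality string to integer scores
#'
#' Each character's ASCII code minus 33 is its score; valid characters are
#' ASCII 33 (`!`, score 0) through 126 (`~`, score 93).
#'
#' @param encoded Character scalar (one quality string).
#' @return Integer vector of scores, one per character.
#' @examples
#' decodeQuality("+5?") # 10 20 30
#' @export
decodeQuality <- function(encoded) {
  if (!is.character(encoded) || length(encoded) != 1L || is.na(encoded)) {
    qs_usage_error("'encoded' must be a single character string")
  }
  codes <- utf8ToInt(encoded)
  bad <- which(codes < 33L | codes > 126L)
  if (length(bad)) {
    qs_data_error(sprintf(
      "malformed quality character at position %d (ASCII %d outside [33, 126])",
      bad[1L], codes[bad[1L]]
    ))
  }
  codes - .QS_OFFSET
}

#' Encode integer scores as a Phred+33 quality string
#'
#' Exact inverse of [decodeQuality()] on the valid domain.
#'
#' @param scores Integer vector with values in \[0, 93\].
#' @return Character scalar of length `length(scores)`.
#' @examples
#' encodeQuality(c(10L, 10L, 10L)) # "+++"
#' @export
encodeQuality <- function(scores) {
  s <- .checkScores(scores)
  if (length(s) == 0L) return("")
  intToUtf8(s + .QS_OFFSET)
}
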
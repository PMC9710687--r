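#' @include FastqReads.R
NULL

# gzip detection by magic bytes (0x1f 0x8b), not file extension, so renamed
# files are handled correctly.
.isGzip <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 2L)
  length(magic) == 2L && magic[1L] == as.raw(0x1f) && magic[2L] == as.raw(0x8b)
}

.openFastqInput <- function(input, gzipAuto = TRUE) {
  if (inherits(input, "connection")) {
    if (!isOpen(input)) open(input, "rt")
    return(list(con = input, own = FALSE))
  }
  if (!is.character(input) || length(input) != 1L) {
    qs_usage_error("'input' must be a file path or a connection")
  }
  if (!file.exists(input)) {
    qs_data_error(sprintf("input file '%s' does not exist", input))
  }
  con <- if (gzipAuto && .isGzip(input)) gzfile(input, "rt") else file(input, "rt")
  list(con = con, own = TRUE)
}

# Parse 4k raw FASTQ lines (k complete records) into a FastqReads chunk,
# validating the '@'/'+' markers and length agreement. 'offset' is the number
# of records already consumed, used for error ordinals.
.parseFastqLines <- function(lines, offset) {
  n <- length(lines) %/% 4L
  idx <- seq_len(n)
  l1 <- lines[4L * idx - 3L]
  l2 <- lines[4L * idx - 2L]
  l3 <- lines[4L * idx - 1L]
  l4 <- lines[4L * idx]
  bad <- which(substr(l1, 1L, 1L) != "@")
  if (length(bad)) {
    qs_data_error(sprintf(
      "record %d: header line does not start with '@'", offset + bad[1L]
    ))
  }
  bad <- which(substr(l3, 1L, 1L) != "+")
  if (length(bad)) {
    qs_data_error(sprintf(
      "record %d: separator line does not start with '+'", offset + bad[1L]
    ))
  }
  bad <- which(nchar(l2, type = "bytes") != nchar(l4, type = "bytes"))
  if (length(bad)) {
    qs_data_error(sprintf(
      "record %d: sequence length %d != quality length %d",
      offset + bad[1L], nchar(l2[bad[1L]]), nchar(l4[bad[1L]])
    ))
  }
  bad <- which(grepl("[^\x21-\x7e]", l4, perl = TRUE, useBytes = TRUE))
  if (length(bad)) {
    codes <- utf8ToInt(l4[bad[1L]])
    pos <- which(codes < 33L | codes > 126L)[1L]
    qs_data_error(sprintf(
      "record %d: malformed quality character at position %d (ASCII %d outside [33, 126])",
      offset + bad[1L], pos, codes[pos]
    ))
  }
  new("FastqReads",
    header = substring(l1, 2L), sequence = l2,
    separator = substring(l3, 2L), quality = l4
  )
}

#' Stream a FASTQ file chunk by chunk
#'
#' Reads 4-line FASTQ records from `input` (plain or gzip, detected by magic
#' bytes) and calls `FUN` on successive [FastqReads-class] chunks of at most
#' `chunkSize` records. Memory use is bounded by the chunk, not the file, so
#' arbitrarily large files can be transformed record-by-record.
#'
#' @param input File path or text connection.
#' @param FUN Function of one argument (a `FastqReads` chunk); its return
#'   value is discarded.
#' @param chunkSize Maximum records per chunk (default 10000).
#' @param gzipAuto Detect and transparently decompress gzip input (default
#'   `TRUE`).
#' @return Invisibly, the total number of records processed.
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' writeFastq(FastqReads("r1", "ACGT", "", list(c(1L, 2L, 3L, 4L))), fq)
#' streamFastq(fq, function(chunk) message(length(chunk), " reads"))
#' @export
streamFastq <- function(input, FUN, chunkSize = 10000L, gzipAuto = TRUE) {
  stopifnot(is.function(FUN))
  if (!is.numeric(chunkSize) || chunkSize < 1L) {
    qs_usage_error("'chunkSize' must be a positive integer")
  }
  src <- .openFastqInput(input, gzipAuto)
  if (src$own) on.exit(close(src$con))
  total <- 0L
  repeat {
    lines <- readLines(src$con, n = 4L * as.integer(chunkSize))
    if (length(lines) == 0L) break
    if (length(lines) %% 4L != 0L) {
      qs_data_error(sprintf(
        "truncated FASTQ: record %d ends mid-record (file has %d trailing line%s)",
        total + length(lines) %/% 4L + 1L, length(lines) %% 4L,
        if (length(lines) %% 4L == 1L) "" else "s"
      ))
    }
    chunk <- .parseFastqLines(lines, total)
    FUN(chunk)
    total <- total + length(chunk)
    if (length(lines) < 4L * chunkSize) break
  }
  invisible(total)
}

#' Read a FASTQ file
#'
#' Parses a 4-line-per-record FASTQ file, plain or gzip-compressed (detected
#' by magic bytes regardless of extension), into a [FastqReads-class]
#' object. Wrapped multi-line FASTQ is not supported: nanopore basecallers
#' emit strict 4-line records, and the restriction removes the classic
#' `+`-line parsing ambiguity.
#'
#' @inheritParams streamFastq
#' @return A [FastqReads-class] object.
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1", "ACGT", "+", "IIII"), fq)
#' readFastq(fq)
#' @export
readFastq <- function(input, gzipAuto = TRUE) {
  chunks <- list()
  streamFastq(input, function(chunk) {
    chunks[[length(chunks) + 1L]] <<- chunk
  }, gzipAuto = gzipAuto)
  if (length(chunks) == 0L) {
    return(FastqReads())
  }
  do.call(c, chunks)
}

#' Write reads as 4-line FASTQ
#'
#' Emits one `@header`/sequence/`+separator`/quality quadruple per read.
#' Headers and separators are written verbatim, so parse-then-write of a
#' 4-line FASTQ file reproduces it byte for byte.
#'
#' @param reads A [FastqReads-class] object.
#' @param sink Output file path or writable text connection.
#' @param gzip Compress the output with gzip. Default: `TRUE` when `sink` is
#'   a path ending in `.gz`.
#' @return Invisibly, the number of records written.
#' @examples
#' fq <- tempfile(fileext = ".fastq.gz")
#' writeFastq(FastqReads("r1", "ACGT", "", list(c(1L, 2L, 3L, 4L))), fq)
#' readFastq(fq)
#' @export
writeFastq <- function(reads, sink, gzip = NULL) {
  stopifnot(is(reads, "FastqReads"))
  if (inherits(sink, "connection")) {
    con <- sink
    own <- FALSE
    if (!isOpen(con)) {
      open(con, "wt")
      own <- TRUE
    }
  } else {
    if (!is.character(sink) || length(sink) != 1L) {
      qs_usage_error("'sink' must be a file path or a connection")
    }
    if (is.null(gzip)) gzip <- grepl("\\.gz$", sink)
    con <- tryCatch(
      if (gzip) gzfile(sink, "wt") else file(sink, "wt"),
      error = function(e) qs_data_error(sprintf("cannot open '%s' for writing", sink)),
      warning = function(w) qs_data_error(sprintf("cannot open '%s' for writing", sink))
    )
    own <- TRUE
  }
  if (own) on.exit(close(con))
  n <- length(reads)
  if (n > 0L) {
    lines <- character(4L * n)
    idx <- seq_len(n)
    lines[4L * idx - 3L] <- paste0("@", reads@header)
    lines[4L * idx - 2L] <- reads@sequence
    lines[4L * idx - 1L] <- paste0("+", reads@separator)
    lines[4L * idx] <- reads@quality
    writeLines(lines, con)
  }
  invisible(n)
}

#' Downsample reads to an exact fraction
#'
#' Selects exactly `round(fraction * N)` of the `N` input reads (ties rounded
#' half-up), uniformly without replacement, preserving input order. The
#' selection is driven entirely by `seed`, so identical input, fraction and
#' seed always reproduce the same subset -- the mechanism used to emulate
#' reduced coverage (e.g. 10%, 20%, 60% of a dataset's reads).
#'
#' @param reads A [FastqReads-class] object.
#' @param fraction Real in \[0, 1\]: the fraction of reads to keep.
#' @param seed Integer seed for the selection.
#' @return A [FastqReads-class] subset in original order.
#' @examples
#' reads <- simulateFastq(nReads = 10, meanLength = 50, seed = 1)$reads
#' length(downsampleReads(reads, 0.5, seed = 42))
#' @export
downsampleReads <- function(reads, fraction, seed) {
  stopifnot(is(reads, "FastqReads"))
  if (!is.numeric(fraction) || length(fraction) != 1L || is.na(fraction) ||
      fraction < 0 || fraction > 1) {
    qs_usage_error("'fraction' must be a single number in [0, 1]")
  }
  n <- length(reads)
  # half-up with a guard against binary representation error (0.35 * 10 is
  # 3.4999999999999996 in double arithmetic)
  k <- as.integer(floor(fraction * n + 0.5 + 1e-9))
  if (k == 0L) return(reads[integer(0)])
  if (k == n) return(reads)
  idx <- withSeed(seed, sort(sample.int(n, k)))
  reads[idx]
}
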
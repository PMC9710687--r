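#' @include metrics.R
NULL

# Byte size of a file's uncompressed content: plain files as-is, gzip files
# (by magic bytes) measured through the decompressing connection.
.uncompressedSize <- function(path) {
  if (!file.exists(path)) qs_data_error(sprintf("file '%s' does not exist", path))
  if (!.isGzip(path)) return(file.size(path))
  con <- gzfile(path, "rb")
  on.exit(close(con))
  total <- 0
  repeat {
    chunk <- readBin(con, "raw", n = 1048576L)
    if (length(chunk) == 0L) break
    total <- total + length(chunk)
  }
  total
}

#' Compress a file with the gzip codec
#'
#' Streams `path` (decompressing first if it is already gzip) through R's
#' zlib-based gzip codec at the given compression level and returns the
#' compressed byte count. Used to measure compression ratios reproducibly
#' within one codec version; absolute byte counts may differ from other gzip
#' implementations, ratios are what get compared.
#'
#' @param path Input file.
#' @param destination Output path for the compressed bytes; defaults to a
#'   temporary file that is deleted before returning.
#' @param level gzip compression level 1--9 (default 6, the codec default).
#' @return Number of compressed bytes.
#' @examples
#' f <- tempfile()
#' writeLines(rep("AAAA", 100), f)
#' gzipFileSize(f) < file.size(f)
#' @export
gzipFileSize <- function(path, destination = NULL, level = 6L) {
  if (!file.exists(path)) qs_data_error(sprintf("file '%s' does not exist", path))
  keep <- !is.null(destination)
  if (!keep) destination <- tempfile(fileext = ".gz")
  inCon <- if (.isGzip(path)) gzfile(path, "rb") else file(path, "rb")
  outCon <- gzfile(destination, "wb", compression = as.integer(level))
  on.exit({
    close(inCon)
    close(outCon)
    if (!keep && file.exists(destination)) unlink(destination)
  })
  repeat {
    chunk <- readBin(inCon, "raw", n = 1048576L)
    if (length(chunk) == 0L) break
    writeBin(chunk, outCon)
  }
  close(outCon)
  on.exit({
    close(inCon)
    if (!keep && file.exists(destination)) unlink(destination)
  })
  file.size(destination)
}

#' Compression-ratio report for a set of FASTQ files
#'
#' For each file: its uncompressed size, its gzip-compressed size (measured
#' with R's zlib codec at `level`), the compression ratio, and the percent
#' space saving relative to the first-listed file's compressed size (the
#' baseline, conventionally the non-quantized data). Gzip inputs are
#' transparently decompressed before measuring, so already-compressed and
#' plain variants are compared on equal footing.
#'
#' @param paths Character vector of FASTQ file paths; the first is the
#'   baseline.
#' @param labels Row labels (default: file base names).
#' @param level gzip compression level (default 6).
#' @return `data.frame` with columns `label`, `original_bytes`,
#'   `compressed_bytes`, `cr`, `saving_percent` (baseline saving is 0).
#' @examples
#' sim <- simulateFastq(nReads = 50, meanLength = 80, seed = 7)
#' orig <- tempfile(fileext = ".fastq")
#' writeFastq(sim$reads, orig)
#' quant <- tempfile(fileext = ".fastq")
#' writeFastq(quantizeReads(builtinQuantizer("Q2"), sim$reads), quant)
#' compressReport(c(orig, quant), labels = c("Original", "Q2"))
#' @export
compressReport <- function(paths, labels = basename(paths), level = 6L) {
  if (length(paths) == 0L) qs_usage_error("at least one input file is required")
  if (length(labels) != length(paths)) {
    qs_usage_error("'labels' must match 'paths' in length")
  }
  original <- vapply(paths, .uncompressedSize, numeric(1))
  compressed <- vapply(paths, gzipFileSize, numeric(1), level = level)
  data.frame(
    label = labels,
    original_bytes = unname(original),
    compressed_bytes = unname(compressed),
    cr = compressionRatio(original, compressed),
    saving_percent = spaceSavingPercent(compressed[1L], compressed),
    row.names = NULL
  )
}
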
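#' @include qsquant-package.R
NULL

#' Recall, precision and F1 from confusion counts
#'
#' `Rec = TP / (TP + FN)`, `Prec = TP / (TP + FP)`,
#' `F1 = 2 * Prec * Rec / (Prec + Rec)`, the summary used for variant-calling
#' benchmarks. Degenerate denominators follow the usual reporting
#' convention: a metric whose denominator is 0 is reported as 0, and `F1 = 0`
#' when `Prec + Rec = 0`, keeping the function total. Values are returned at
#' full precision; use [roundHalfUp()] for 4-decimal table display.
#'
#' @param tp,fp,fn Non-negative integer vectors (recycled to common length):
#'   true-positive, false-positive and false-negative counts.
#' @return `data.frame` with columns `rec`, `prec`, `f1`.
#' @examples
#' metricsFromCounts(tp = 3317116, fp = 10041, fn = 10376)
#' @export
metricsFromCounts <- function(tp, fp, fn) {
  n <- max(length(tp), length(fp), length(fn))
  tp <- rep_len(as.numeric(tp), n)
  fp <- rep_len(as.numeric(fp), n)
  fn <- rep_len(as.numeric(fn), n)
  if (anyNA(tp) || anyNA(fp) || anyNA(fn)) {
    qs_data_error("confusion counts must not contain NA")
  }
  if (any(tp < 0) || any(fp < 0) || any(fn < 0)) {
    qs_data_error("confusion counts must be non-negative")
  }
  rec <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  data.frame(rec = rec, prec = prec, f1 = f1)
}

#' F1 score from precision and recall
#'
#' Harmonic mean of precision and recall; 0 when both are 0.
#'
#' @param prec,rec Numeric vectors in \[0, 1\] (recycled).
#' @return Numeric vector of F1 scores.
#' @examples
#' f1FromPR(0.9136, 0.6016)
#' @export
f1FromPR <- function(prec, rec) {
  n <- max(length(prec), length(rec))
  prec <- rep_len(as.numeric(prec), n)
  rec <- rep_len(as.numeric(rec), n)
  if (anyNA(prec) || anyNA(rec) ||
      any(prec < 0 | prec > 1) || any(rec < 0 | rec > 1)) {
    qs_data_error("'prec' and 'rec' must lie in [0, 1]")
  }
  ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
}

#' Compression ratio
#'
#' Quotient of compressed over original (uncompressed) size; smaller ratios
#' mean better compression.
#'
#' @param originalBytes Positive number: uncompressed size in bytes.
#' @param compressedBytes Non-negative number: compressed size in bytes.
#' @return Numeric: `compressedBytes / originalBytes`.
#' @examples
#' compressionRatio(1000, 250)
#' @export
compressionRatio <- function(originalBytes, compressedBytes) {
  if (any(!is.finite(originalBytes)) || any(originalBytes <= 0)) {
    qs_data_error("'originalBytes' must be positive")
  }
  if (any(!is.finite(compressedBytes)) || any(compressedBytes < 0)) {
    qs_data_error("'compressedBytes' must be non-negative")
  }
  compressedBytes / originalBytes
}

#' Percent space saving versus a compressed baseline
#'
#' `100 * (baseline - variant) / baseline`: how much smaller a variant's
#' compressed size is than the baseline's compressed size. Negative when the
#' variant compresses worse.
#'
#' @param baselineCompressedBytes Positive number: compressed size of the
#'   baseline (e.g. the original, non-quantized data).
#' @param variantCompressedBytes Non-negative number: compressed size of the
#'   variant (e.g. quantized data).
#' @return Numeric percent saving.
#' @examples
#' spaceSavingPercent(100, 60) # 40
#' @export
spaceSavingPercent <- function(baselineCompressedBytes, variantCompressedBytes) {
  if (any(!is.finite(baselineCompressedBytes)) || any(baselineCompressedBytes <= 0)) {
    qs_data_error("'baselineCompressedBytes' must be positive")
  }
  if (any(!is.finite(variantCompressedBytes)) || any(variantCompressedBytes < 0)) {
    qs_data_error("'variantCompressedBytes' must be non-negative")
  }
  100 * (baselineCompressedBytes - variantCompressedBytes) / baselineCompressedBytes
}

#' Zeroth-order empirical entropy of a score sequence
#'
#' `-sum(p * log2(p))` over the empirical symbol distribution: a lower bound
#' (in bits per symbol) on what a memoryless compressor can achieve, and a
#' quick diagnostic of how much a quantizer reduces quality-string
#' information. Deterministic quantization merges symbols, so it can never
#' increase this entropy.
#'
#' @param scores Non-empty integer vector of quality scores.
#' @return Numeric scalar in `[0, log2(94)]` bits per symbol.
#' @examples
#' empiricalEntropy(rep(c(5L, 15L), 50)) # 1 bit
#' @export
empiricalEntropy <- function(scores) {
  if (length(scores) == 0L) qs_data_error("'scores' must be non-empty")
  s <- .checkScores(scores)
  p <- tabulate(s + 1L, nbins = .QS_MAX + 1L)
  p <- p[p > 0] / length(s)
  -sum(p * log2(p))
}

#' Read a confusion-counts table
#'
#' Parses a delimited text table with columns `label`, `tp`, `fp`, `fn`
#' (header required; tab- or whitespace-separated).
#'
#' @param path File path.
#' @return `data.frame` with the four columns, counts as numbers.
#' @export
readCountsTable <- function(path) {
  if (!file.exists(path)) qs_data_error(sprintf("counts file '%s' does not exist", path))
  tab <- tryCatch(
    read.table(path, header = TRUE, sep = "", stringsAsFactors = FALSE),
    error = function(e) qs_data_error(sprintf("cannot parse counts table: %s", conditionMessage(e)))
  )
  need <- c("label", "tp", "fp", "fn")
  if (!all(need %in% names(tab))) {
    qs_data_error(sprintf(
      "counts table must have columns %s", paste(need, collapse = ", ")
    ))
  }
  for (col in c("tp", "fp", "fn")) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v) | v < 0)
    if (length(bad)) {
      qs_data_error(sprintf("row %d: invalid %s count '%s'", bad[1L], col, tab[[col]][bad[1L]]))
    }
    tab[[col]] <- v
  }
  tab[need]
}
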
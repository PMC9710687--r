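# Brute-force oracles for repeat detection, written against the literal
# definitions (scan every start position, extend, record qualifying
# substrings) and kept independent of the package's rle-based implementation.

oracleHomopolymers <- function(sequence, h) {
  codes <- utf8ToInt(toupper(sequence))
  n <- length(codes)
  out <- data.frame(start = integer(0), end = integer(0), kind = character(0))
  s <- 1L
  while (s <= n) {
    e <- s
    while (e < n && codes[e + 1L] == codes[s]) e <- e + 1L
    if (e - s + 1L >= h) {
      out <- rbind(out, data.frame(
        start = s - 1L, end = e, kind = "homopolymer"
      ))
    }
    s <- e + 1L
  }
  out
}

# Every substring that is >= d copies of a distinct-letter pair marks its
# positions; maximal flagged stretches are the merged intervals.
oracleDinucleotide <- function(sequence, d) {
  codes <- utf8ToInt(toupper(sequence))
  n <- length(codes)
  flagged <- rep(FALSE, n)
  if (n >= 2L * d) {
    for (s in seq_len(n - 2L * d + 1L)) {
      a <- codes[s]
      b <- codes[s + 1L]
      if (a == b) next
      k <- 1L
      while (s + 2L * k + 1L <= n &&
             codes[s + 2L * k] == a && codes[s + 2L * k + 1L] == b) {
        k <- k + 1L
      }
      if (k >= d) flagged[s:(s + 2L * k - 1L)] <- TRUE
    }
  }
  maskToIntervals(flagged, kind = "dinucleotide")
}

maskToIntervals <- function(mask, kind = NA_character_) {
  out <- data.frame(start = integer(0), end = integer(0), kind = character(0))
  if (!any(mask)) return(out)
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(start = starts[keep] - 1L, end = ends[keep], kind = kind)
}

oracleMask <- function(sequence, h, d, delta) {
  n <- nchar(sequence)
  iv <- rbind(oracleHomopolymers(sequence, h), oracleDinucleotide(sequence, d))
  mask <- rep(FALSE, n)
  for (i in seq_len(nrow(iv))) {
    for (j in seq_len(n)) {
      if (iv$start[i] - delta <= j - 1L && j - 1L <= iv$end[i] - 1L + delta) {
        mask[j] <- TRUE
      }
    }
  }
  mask
}

randomSequence <- function(n, alphabet = c("A", "C", "G", "T", "N")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Random valid interval quantizer: random bin edges over [0, 93], each
# representative drawn inside its bin (values are then strictly increasing
# by construction).
randomIntervalQuantizer <- function(maxBins = 8L) {
  k <- sample.int(maxBins, 1L)
  cuts <- if (k > 1L) sort(sample(1:93, k - 1L)) else integer(0)
  low <- c(0L, cuts)
  high <- c(cuts - 1L, 93L)
  value <- vapply(seq_len(k), function(i) {
    if (low[i] == high[i]) low[i] else sample(low[i]:high[i], 1L)
  }, integer(1))
  IntervalQuantizer(low, high, value)
}

# A small well-formed FASTQ written to a temp file; returns the path.
writeTempFastq <- function(reads, gz = FALSE) {
  path <- tempfile(fileext = if (gz) ".fastq.gz" else ".fastq")
  writeFastq(reads, path)
  path
}
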
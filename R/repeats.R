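#' @include quantizers.R FastqReads.R
NULL

#' Two-regime repeat-context quantizer
#'
#' Nanopore basecalls are least reliable in and around repetitive sequence,
#' so this quantizer keeps two position-independent quantizers and switches
#' between them by context: `far` is applied to a score whose read position
#' is more than `delta` bases away from every repetitive interval, `near`
#' everywhere else. A repetitive interval is a homopolymer of at least `h`
#' bases or at least `d` consecutive copies of a two-letter unit with
#' distinct letters. Defaults are `h = 5`, `d = 4`, `delta = 5`.
#'
#' @slot far,near [ScoreQuantizer-class] objects.
#' @slot h Integer >= 2: minimum homopolymer length.
#' @slot d Integer >= 2: minimum dinucleotide copy count.
#' @slot delta Integer >= 0: context half-width around repeat intervals.
#'
#' @seealso [ContextQuantizer()], [repeatMask()], [quantizeReads()]
#' @name ContextQuantizer-class
#' @exportClass ContextQuantizer
setClass("ContextQuantizer",
  representation(
    far = "ScoreQuantizer", near = "ScoreQuantizer",
    h = "integer", d = "integer", delta = "integer"
  )
)

setValidity("ContextQuantizer", function(object) {
  if (length(object@h) != 1L || is.na(object@h) || object@h < 2L) {
    return("'h' must be a single integer >= 2")
  }
  if (length(object@d) != 1L || is.na(object@d) || object@d < 2L) {
    return("'d' must be a single integer >= 2")
  }
  if (length(object@delta) != 1L || is.na(object@delta) || object@delta < 0L) {
    return("'delta' must be a single integer >= 0")
  }
  TRUE
})

#' Create a repeat-context quantizer
#'
#' @param far Quantizer (object or spec string, see [parseQuantizerSpec()])
#'   applied to scores more than `delta` bases from any repeat.
#' @param near Quantizer applied within or near repeats.
#' @param delta Context half-width in bases (default 5).
#' @param h Minimum homopolymer length (default 5).
#' @param d Minimum dinucleotide copy count (default 4).
#' @return A [ContextQuantizer-class] object.
#' @examples
#' cq <- ContextQuantizer(far = "F:10", near = "Q8")
#' reads <- FastqReads("r", "TTGCAAAAAGCA", "", list(rep(30L, 12)))
#' qualityScores(quantizeReads(cq, reads))
#' @export
ContextQuantizer <- function(far, near, delta = 5L, h = 5L, d = 4L) {
  if (is.character(far)) far <- parseQuantizerSpec(far)
  if (is.character(near)) near <- parseQuantizerSpec(near)
  new("ContextQuantizer",
    far = far, near = near,
    h = as.integer(h), d = as.integer(d), delta = as.integer(delta)
  )
}

setMethod("show", "ContextQuantizer", function(object) {
  cat(sprintf(
    "ContextQuantizer <far, near>delta with h = %d, d = %d, delta = %d\n",
    object@h, object@d, object@delta
  ))
  cat(sprintf("  far  (away from repeats): %s\n", formatQuantizerSpec(object@far)))
  cat(sprintf("  near (within/close)     : %s\n", formatQuantizerSpec(object@near)))
  invisible(object)
})

.emptyIntervals <- function() {
  data.frame(start = integer(0), end = integer(0), kind = character(0))
}

.checkSequenceArg <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence)) {
    qs_usage_error("'sequence' must be a single character string")
  }
}

#' Find homopolymer runs
#'
#' Returns every maximal run of one repeated letter of length at least `h`,
#' case-insensitively; `N` (or any letter) participates like any other.
#' Coordinates are 0-based, half-open.
#'
#' @param sequence Character scalar of bases.
#' @param h Minimum run length (integer >= 2, default 5).
#' @return `data.frame` with columns `start`, `end` (0-based, half-open) and
#'   `kind` (always `"homopolymer"`), intervals in ascending order.
#' @examples
#' findHomopolymerRuns("AAAACCCCC", h = 5) # the C run only
#' @export
findHomopolymerRuns <- function(sequence, h = 5L) {
  .checkSequenceArg(sequence)
  h <- as.integer(h)
  if (is.na(h) || h < 2L) qs_usage_error("'h' must be an integer >= 2")
  n <- nchar(sequence)
  if (n < h) return(.emptyIntervals())
  codes <- utf8ToInt(toupper(sequence))
  r <- rle(codes)
  ends <- cumsum(r$lengths)
  keep <- r$lengths >= h
  if (!any(keep)) return(.emptyIntervals())
  data.frame(
    start = (ends - r$lengths)[keep],
    end = ends[keep],
    kind = "homopolymer"
  )
}

#' Find dinucleotide repeats
#'
#' Returns every maximal interval consisting of at least `d` consecutive
#' copies of a two-letter unit whose letters differ (e.g. `ACACACAC` for
#' `d = 4`), considering both phase offsets; overlapping intervals from
#' different units are merged. Equal-letter units (`AA`) are excluded: those
#' regions are homopolymers and are governed by `h`. Case-insensitive;
#' 0-based, half-open coordinates.
#'
#' @param sequence Character scalar of bases.
#' @param d Minimum number of unit copies (integer >= 2, default 4).
#' @return `data.frame` with columns `start`, `end`, `kind`
#'   (always `"dinucleotide"`), intervals ascending and non-overlapping.
#' @examples
#' findDinucleotideRepeats("TACACACACG", d = 4) # [1, 9)
#' @export
findDinucleotideRepeats <- function(sequence, d = 4L) {
  .checkSequenceArg(sequence)
  d <- as.integer(d)
  if (is.na(d) || d < 2L) qs_usage_error("'d' must be an integer >= 2")
  n <- nchar(sequence)
  if (n < 2L * d) return(.emptyIntervals())
  codes <- utf8ToInt(toupper(sequence))
  # A maximal period-2 region is a maximal run of codes[i] == codes[i + 2].
  # Within one region the sequence is determined by its first two letters;
  # requiring them to differ excludes homopolymers. A region of length L
  # contains floor(L / 2) complete unit copies at each phase, and when that
  # count reaches d the union of the copy intervals over both phases covers
  # the whole region.
  eq2 <- codes[seq_len(n - 2L)] == codes[3:n]
  r <- rle(eq2)
  runEnds <- cumsum(r$lengths)
  runStarts <- runEnds - r$lengths + 1L
  keep <- which(r$values)
  out <- .emptyIntervals()
  for (k in keep) {
    s <- runStarts[k]                 # 1-based start of region
    L <- r$lengths[k] + 2L            # region covers s .. s + L - 1
    if (codes[s] == codes[s + 1L]) next
    if (L %/% 2L < d) next
    out <- rbind(out, data.frame(
      start = s - 1L, end = s - 1L + L, kind = "dinucleotide"
    ))
  }
  if (nrow(out) <= 1L) return(out)
  # adjacent qualifying regions (e.g. "ACACGTGT" with d = 2) flag a
  # contiguous stretch of positions; the canonical report is its maximal
  # intervals, so touching regions are fused like overlapping ones
  .mergeIntervals(out, adjacent = TRUE)
}

# Merge sorted intervals; adjacent = TRUE also fuses touching intervals.
# Kinds of merged intervals are joined with "," (unique, sorted).
.mergeIntervals <- function(iv, adjacent = TRUE) {
  if (nrow(iv) <= 1L) return(iv)
  iv <- iv[order(iv$start, iv$end), , drop = FALSE]
  starts <- iv$start[1L]
  ends <- iv$end[1L]
  kinds <- list(iv$kind[1L])
  for (i in 2L:nrow(iv)) {
    j <- length(starts)
    touches <- if (adjacent) iv$start[i] <= ends[j] else iv$start[i] < ends[j]
    if (touches) {
      ends[j] <- max(ends[j], iv$end[i])
      kinds[[j]] <- c(kinds[[j]], iv$kind[i])
    } else {
      starts <- c(starts, iv$start[i])
      ends <- c(ends, iv$end[i])
      kinds[[length(kinds) + 1L]] <- iv$kind[i]
    }
  }
  data.frame(
    start = starts, end = ends,
    kind = vapply(kinds, function(k) paste(sort(unique(k)), collapse = ","), character(1))
  )
}

#' All repetitive intervals of a sequence
#'
#' Union of [findHomopolymerRuns()] and [findDinucleotideRepeats()];
#' overlapping or adjacent intervals are merged into canonical form (the
#' `kind` column then lists the contributing kinds, comma-separated).
#'
#' @inheritParams findHomopolymerRuns
#' @inheritParams findDinucleotideRepeats
#' @param merge Merge overlapping/adjacent intervals (default `TRUE`).
#' @return `data.frame` with columns `start`, `end`, `kind`, ascending.
#' @examples
#' repeatIntervals("AAAAACACACACA", h = 5, d = 4)
#' @export
repeatIntervals <- function(sequence, h = 5L, d = 4L, merge = TRUE) {
  iv <- rbind(findHomopolymerRuns(sequence, h), findDinucleotideRepeats(sequence, d))
  iv <- iv[order(iv$start, iv$end), , drop = FALSE]
  rownames(iv) <- NULL
  if (merge) .mergeIntervals(iv) else iv
}

#' Per-position repeat-context mask
#'
#' Position `j` (0-based) is flagged when its distance to the closest base of
#' any repetitive interval is at most `delta`: for an interval `[s, e)` the
#' flagged range is `s - delta .. e - 1 + delta`, clamped to the read.
#'
#' @inheritParams repeatIntervals
#' @param delta Context half-width in bases (integer >= 0, default 5).
#' @return Logical vector, one flag per base; `TRUE` means within/near a
#'   repeat (the `near` regime of a [ContextQuantizer-class]).
#' @examples
#' which(repeatMask("ACGTACGTAAAAAGT", delta = 2))
#' @export
repeatMask <- function(sequence, h = 5L, d = 4L, delta = 5L) {
  delta <- as.integer(delta)
  if (is.na(delta) || delta < 0L) qs_usage_error("'delta' must be an integer >= 0")
  n <- nchar(sequence)
  mask <- rep.int(FALSE, n)
  iv <- repeatIntervals(sequence, h, d)
  for (i in seq_len(nrow(iv))) {
    lo <- max(iv$start[i] - delta, 0L) + 1L
    hi <- min(iv$end[i] - 1L + delta, n - 1L) + 1L
    mask[lo:hi] <- TRUE
  }
  mask
}

#' @rdname quantizeReads
#' @aliases quantizeReads,ContextQuantizer-method
setMethod("quantizeReads", "ContextQuantizer", function(x, reads) {
  stopifnot(is(reads, "FastqReads"))
  farCodes <- scoreMap(x@far) + .QS_OFFSET
  nearCodes <- scoreMap(x@near) + .QS_OFFSET
  quality <- vapply(seq_len(length(reads)), function(i) {
    qual <- reads@quality[i]
    if (nchar(qual) == 0L) return(qual)
    codes <- utf8ToInt(qual) - 32L # 1-based index into the 94-entry maps
    mask <- repeatMask(reads@sequence[i], x@h, x@d, x@delta)
    out <- farCodes[codes]
    if (any(mask)) out[mask] <- nearCodes[codes[mask]]
    intToUtf8(out)
  }, character(1))
  initialize(reads, quality = quality)
})
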
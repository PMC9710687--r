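#' @include AllGenerics.R
NULL

#' Virtual parent of position-independent score quantizers
#'
#' A `ScoreQuantizer` is a total deterministic map from the nanopore Phred
#' score domain \{0, ..., 93\} to a (usually much smaller) output alphabet
#' within the same domain. Concrete subclasses are
#' [IntervalQuantizer-class] and [ConstantQuantizer-class].
#'
#' @name ScoreQuantizer-class
#' @aliases ScoreQuantizer
#' @exportClass ScoreQuantizer
setClass("ScoreQuantizer", representation("VIRTUAL"))

#' Interval quantizer
#'
#' Partitions the score domain \[0, 93\] into contiguous bins, each mapped to
#' one representative value. Validity enforces that the bins tile \[0, 93\]
#' exactly (no gaps, no overlaps), that representative values are strictly
#' increasing across bins (the map is monotone), and that each value lies
#' inside its own bin -- which makes every interval quantizer idempotent:
#' re-quantizing already-quantized scores is a no-op.
#'
#' @slot low Integer vector of bin lower bounds (first must be 0).
#' @slot high Integer vector of bin upper bounds (last must be 93).
#' @slot value Integer vector of representative values, one per bin.
#'
#' @seealso [IntervalQuantizer()], [builtinQuantizer()], [parseQuantizerSpec()]
#' @name IntervalQuantizer-class
#' @exportClass IntervalQuantizer
setClass("IntervalQuantizer",
  contains = "ScoreQuantizer",
  representation(low = "integer", high = "integer", value = "integer")
)

setValidity("IntervalQuantizer", function(object) {
  low <- object@low
  high <- object@high
  value <- object@value
  n <- length(low)
  if (n == 0L) return("quantizer must have at least one bin")
  if (length(high) != n || length(value) != n) {
    return("'low', 'high' and 'value' must have equal length")
  }
  if (anyNA(low) || anyNA(high) || anyNA(value)) return("bins must not contain NA")
  for (i in seq_len(n)) {
    if (low[i] > high[i]) {
      return(sprintf("bin %d: lower bound %d exceeds upper bound %d", i, low[i], high[i]))
    }
  }
  if (low[1L] != 0L) return(sprintf("bin 1 must start at 0, not %d", low[1L]))
  if (high[n] != .QS_MAX) {
    return(sprintf("last bin must end at %d, not %d", .QS_MAX, high[n]))
  }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      if (low[i + 1L] != high[i] + 1L) {
        return(sprintf(
          "bin %d: must start at %d (previous bin ends at %d), not %d",
          i + 1L, high[i] + 1L, high[i], low[i + 1L]
        ))
      }
      if (value[i + 1L] <= value[i]) {
        return(sprintf(
          "bin %d: value %d is not larger than previous bin's value %d (map must be monotone)",
          i + 1L, value[i + 1L], value[i]
        ))
      }
    }
  }
  for (i in seq_len(n)) {
    if (value[i] < low[i] || value[i] > high[i]) {
      return(sprintf(
        "bin %d: value %d lies outside its interval [%d, %d] (idempotence requires value in bin)",
        i, value[i], low[i], high[i]
      ))
    }
  }
  TRUE
})

#' Constant quantizer
#'
#' Maps every quality score to one fixed value `z`; the output alphabet has
#' size 1. The value 10 is a common read-filtering threshold and the usual
#' experimental choice.
#'
#' @slot z Integer in \[0, 93\].
#'
#' @seealso [ConstantQuantizer()], [builtinQuantizer()]
#' @name ConstantQuantizer-class
#' @exportClass ConstantQuantizer
setClass("ConstantQuantizer",
  contains = "ScoreQuantizer",
  representation(z = "integer")
)

setValidity("ConstantQuantizer", function(object) {
  z <- object@z
  if (length(z) != 1L || is.na(z)) return("'z' must be a single integer")
  if (z < 0L || z > .QS_MAX) {
    return(sprintf("'z' must lie in [0, %d], not %d", .QS_MAX, z))
  }
  TRUE
})

#' Create an interval quantizer
#'
#' @param low,high,value Integer vectors of equal length giving, per bin, the
#'   inclusive score bounds and the representative value. Bins must tile
#'   \[0, 93\] in ascending order with strictly increasing values, each value
#'   inside its bin.
#' @return An [IntervalQuantizer-class] object.
#' @examples
#' q2 <- IntervalQuantizer(low = c(0, 8), high = c(7, 93), value = c(5, 15))
#' quantizeScores(q2, 0:10)
#' @export
IntervalQuantizer <- function(low, high, value) {
  new("IntervalQuantizer",
    low = as.integer(low), high = as.integer(high), value = as.integer(value)
  )
}

#' Create a constant quantizer
#'
#' @param z Integer in \[0, 93\]; every score maps to `z`.
#' @return A [ConstantQuantizer-class] object.
#' @examples
#' quantizeScores(ConstantQuantizer(10), c(0, 50, 93))
#' @export
ConstantQuantizer <- function(z) {
  new("ConstantQuantizer", z = as.integer(z))
}

# Builtin definitions. Q2/Q4/Q8 collapse the large set of high scores into a
# single value and bin the frequent low scores more finely; F10 discards all
# score information.
.BUILTIN_QUANTIZERS <- list(
  Q2 = list(low = c(0L, 8L), high = c(7L, 93L), value = c(5L, 15L)),
  Q4 = list(
    low = c(0L, 8L, 14L, 20L), high = c(7L, 13L, 19L, 93L),
    value = c(5L, 12L, 18L, 24L)
  ),
  Q8 = list(
    low = c(0L, 7L, 12L, 17L, 22L, 27L, 32L, 37L),
    high = c(6L, 11L, 16L, 21L, 26L, 31L, 36L, 93L),
    value = c(5L, 10L, 15L, 20L, 25L, 30L, 35L, 40L)
  )
)

#' Builtin quantizers
#'
#' Returns one of the standard quantizers: `"Q2"` (scores 0--7 to 5, 8--93 to
#' 15), `"Q4"` (0--7 to 5, 8--13 to 12, 14--19 to 18, 20--93 to 24), `"Q8"`
#' (eight 5-wide bins for scores up to 36, outputs 5,10,...,35, and 37--93 to
#' 40), or `"F10"` (every score to 10).
#'
#' @param name One of `"Q2"`, `"Q4"`, `"Q8"`, `"F10"`.
#' @return An [IntervalQuantizer-class] or [ConstantQuantizer-class].
#' @examples
#' builtinQuantizer("Q4")
#' @export
builtinQuantizer <- function(name) {
  if (!is.character(name) || length(name) != 1L) {
    qs_usage_error("'name' must be a single character string")
  }
  if (name == "F10") return(ConstantQuantizer(10L))
  def <- .BUILTIN_QUANTIZERS[[name]]
  if (is.null(def)) {
    qs_usage_error(sprintf(
      "unknown builtin quantizer '%s'; valid names: %s",
      name, paste(c(names(.BUILTIN_QUANTIZERS), "F10"), collapse = ", ")
    ))
  }
  IntervalQuantizer(def$low, def$high, def$value)
}

#' Parse a quantizer specification string
#'
#' Accepted forms:
#' * a builtin name: `Q2`, `Q4`, `Q8` (or `F10`);
#' * `F:<z>` for a constant quantizer, e.g. `F:10`;
#' * a comma-separated list of `<low>-<high>:<value>` bins in ascending
#'   order covering 0--93 exactly, e.g. `0-7:5,8-93:15`.
#'
#' @param spec Character scalar in the grammar above.
#' @return A [ScoreQuantizer-class] object.
#' @examples
#' parseQuantizerSpec("0-6:1,7-93:13")
#' parseQuantizerSpec("F:10")
#' @export
parseQuantizerSpec <- function(spec) {
  if (!is.character(spec) || length(spec) != 1L || is.na(spec)) {
    qs_usage_error("quantizer spec must be a single character string")
  }
  spec <- trimws(spec)
  if (spec %in% c(names(.BUILTIN_QUANTIZERS), "F10")) {
    return(builtinQuantizer(spec))
  }
  if (grepl("^F:", spec)) {
    z <- suppressWarnings(as.integer(sub("^F:", "", spec)))
    if (is.na(z)) qs_usage_error(sprintf("invalid constant quantizer spec '%s'", spec))
    return(ConstantQuantizer(z))
  }
  parts <- strsplit(spec, ",", fixed = TRUE)[[1L]]
  m <- regmatches(parts, regexec("^([0-9]+)-([0-9]+):([0-9]+)$", parts))
  bad <- which(lengths(m) != 4L)
  if (length(bad)) {
    qs_usage_error(sprintf(
      "bin %d ('%s') does not match <low>-<high>:<value>", bad[1L], parts[bad[1L]]
    ))
  }
  mm <- do.call(rbind, m)
  tryCatch(
    IntervalQuantizer(
      low = as.integer(mm[, 2L]), high = as.integer(mm[, 3L]),
      value = as.integer(mm[, 4L])
    ),
    error = function(e) qs_usage_error(sprintf(
      "invalid quantizer spec '%s': %s", spec, conditionMessage(e)
    ))
  )
}

#' Render a quantizer back to its specification string
#'
#' Inverse of [parseQuantizerSpec()] up to builtin-name aliasing.
#'
#' @param x A [ScoreQuantizer-class] object.
#' @return Character scalar in the quantizer spec grammar.
#' @examples
#' formatQuantizerSpec(builtinQuantizer("Q2"))
#' @export
formatQuantizerSpec <- function(x) {
  if (is(x, "ConstantQuantizer")) return(sprintf("F:%d", x@z))
  paste(sprintf("%d-%d:%d", x@low, x@high, x@value), collapse = ",")
}

.checkScores <- function(scores) {
  if (length(scores) == 0L) return(integer(0))
  s <- as.integer(scores)
  if (anyNA(s)) qs_data_error("quality scores must not contain NA")
  bad <- which(s < 0L | s > .QS_MAX)
  if (length(bad)) {
    qs_data_error(sprintf(
      "quality score %d at position %d is outside [0, %d]",
      s[bad[1L]], bad[1L], .QS_MAX
    ))
  }
  s
}

#' @rdname scoreMap
#' @aliases scoreMap,IntervalQuantizer-method
setMethod("scoreMap", "IntervalQuantizer", function(x) {
  rep.int(x@value, x@high - x@low + 1L)
})

#' @rdname scoreMap
#' @aliases scoreMap,ConstantQuantizer-method
setMethod("scoreMap", "ConstantQuantizer", function(x) {
  rep.int(x@z, .QS_MAX + 1L)
})

#' @rdname alphabetSize
#' @aliases alphabetSize,IntervalQuantizer-method
setMethod("alphabetSize", "IntervalQuantizer", function(x) length(x@value))

#' @rdname alphabetSize
#' @aliases alphabetSize,ConstantQuantizer-method
setMethod("alphabetSize", "ConstantQuantizer", function(x) 1L)

#' @rdname quantizeScores
#' @aliases quantizeScores,ScoreQuantizer-method
setMethod("quantizeScores", "ScoreQuantizer", function(x, scores) {
  s <- .checkScores(scores)
  scoreMap(x)[s + 1L]
})

setMethod("show", "IntervalQuantizer", function(object) {
  cat(sprintf(
    "IntervalQuantizer with %d bins over scores [0, %d]\n",
    length(object@value), .QS_MAX
  ))
  for (i in seq_along(object@value)) {
    cat(sprintf("  %2d..%2d -> %d\n", object@low[i], object@high[i], object@value[i]))
  }
  invisible(object)
})

setMethod("show", "ConstantQuantizer", function(object) {
  cat(sprintf("ConstantQuantizer: every score -> %d\n", object@z))
  invisible(object)
})

# Quality strings are rewritten by one integer-lookup pass over the whole
# vector, joined on newline (never a quality character). chartr() is not
# usable here: it treats '-' (ASCII 45, a valid quality character) in the
# source alphabet as a range operator.
.quantizeQualityStrings <- function(x, quality) {
  if (length(quality) == 0L) return(quality)
  lut <- integer(126L)
  lut[10L] <- 10L # newline separator maps to itself
  lut[33:126] <- scoreMap(x) + .QS_OFFSET
  joined <- paste0(paste(quality, collapse = "\n"), "\n#")
  out <- strsplit(intToUtf8(lut[utf8ToInt(joined)]), "\n", fixed = TRUE)[[1L]]
  out[-length(out)]
}

#' @rdname quantizeReads
#' @aliases quantizeReads,ScoreQuantizer-method
setMethod("quantizeReads", "ScoreQuantizer", function(x, reads) {
  initialize(reads, quality = .quantizeQualityStrings(x, reads@quality))
})
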
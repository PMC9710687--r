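#' @include repeats.R fastq-io.R
NULL

#' Default quality-score distribution for simulated reads
#'
#' A two-component negative-binomial mixture over scores 0--93, peaked near
#' scores 10--14 with a thin tail of higher scores -- the qualitative shape
#' of nanopore basecaller output, where low scores dominate. This is a test
#' fixture: it makes no claim of fidelity to any particular instrument.
#'
#' @return Numeric vector of 94 probabilities summing to 1; element `i` is
#'   the probability of score `i - 1`.
#' @examples
#' law <- defaultScoreLaw()
#' which.max(law) - 1 # modal score
#' @export
defaultScoreLaw <- function() {
  s <- 0:93
  p <- 0.85 * dnbinom(s, size = 8, mu = 12) + 0.15 * dnbinom(s, size = 4, mu = 24)
  p / sum(p)
}

.validRepeatPlan <- function(plan) {
  need <- c("read", "kind", "unit", "copies", "pos")
  if (!is.data.frame(plan) || !all(need %in% names(plan))) {
    qs_usage_error(sprintf(
      "'repeatPlan' must be a data.frame with columns %s", paste(need, collapse = ", ")
    ))
  }
  plan
}

.plannedInterval <- function(kind, unit, copies, pos) {
  width <- nchar(unit) * copies
  c(start = pos, end = pos + width)
}

# iid background bases as integer codes (utf8 of A,C,G,T)
.BASE_CODES <- utf8ToInt("ACGT")

# Detect repeats on integer base codes; returns TRUE when the read is free of
# homopolymers >= h and dinucleotide repeats >= d copies outside 'allowed'
# (a data.frame of planted intervals, 0-based half-open) and every allowed
# interval is recovered exactly.
.truthMatches <- function(sequence, h, d, planted) {
  found <- rbind(
    findHomopolymerRuns(sequence, h),
    findDinucleotideRepeats(sequence, d)
  )
  found <- found[order(found$start), , drop = FALSE]
  if (nrow(found) != nrow(planted)) return(FALSE)
  if (nrow(found) == 0L) return(TRUE)
  planted <- planted[order(planted$start), , drop = FALSE]
  all(found$start == planted$start) && all(found$end == planted$end) &&
    all(found$kind == planted$kind)
}

#' Simulate nanopore-like FASTQ reads with planted repeats
#'
#' Generates `nReads` reads with negative-binomial lengths, i.i.d. background
#' bases over `A,C,G,T`, and quality scores drawn i.i.d. from `scoreLaw`.
#' Repetitive intervals listed in `repeatPlan` are planted verbatim; each
#' read is then rejection-checked so that the homopolymer/dinucleotide
#' detectors (at thresholds `h`, `d`) recover exactly the planted intervals
#' and nothing else -- the returned ground truth is therefore exhaustive, and
#' detector tests can assert exact equality instead of fuzzy overlap.
#'
#' Rejection makes long repeat-free reads exponentially unlikely, so the
#' default length law is far shorter than real nanopore reads; see the
#' package vignette for what this fixture does and does not emulate.
#'
#' @param nReads Number of reads (>= 0).
#' @param meanLength,dispersion Negative-binomial read-length law
#'   (`mu`, `size`); lengths are clamped to a minimum of 1. Defaults 250 and 6.
#' @param scoreLaw Probability vector over scores 0--93 (default
#'   [defaultScoreLaw()]).
#' @param repeatPlan Optional `data.frame` with columns `read` (1-based read
#'   index), `kind` (`"homopolymer"` or `"dinucleotide"`), `unit` (1 letter,
#'   or 2 distinct letters), `copies` (>= `h`, resp. >= `d`) and `pos`
#'   (0-based start, clamped to fit the read).
#' @param seed Integer seed; the full output is a deterministic function of
#'   the configuration and this seed.
#' @param h,d Detector thresholds the background must stay below (defaults 5
#'   and 4).
#' @param maxAttempts Rejection attempts per read before giving up
#'   (default 1000).
#' @return A list with components `reads` (a [FastqReads-class]) and `truth`
#'   (`data.frame` with columns `read`, `start`, `end`, `kind`; 0-based
#'   half-open intervals of all planted repeats).
#' @examples
#' plan <- data.frame(
#'   read = 1, kind = "homopolymer", unit = "A", copies = 6, pos = 10
#' )
#' sim <- simulateFastq(nReads = 1, meanLength = 50, repeatPlan = plan, seed = 3)
#' sim$truth
#' findHomopolymerRuns(readSequences(sim$reads)[1], h = 5)
#' @export
simulateFastq <- function(nReads, meanLength = 250, dispersion = 6,
                          scoreLaw = defaultScoreLaw(), repeatPlan = NULL,
                          seed, h = 5L, d = 4L, maxAttempts = 1000L) {
  if (!is.numeric(nReads) || length(nReads) != 1L || is.na(nReads) || nReads < 0) {
    qs_usage_error("'nReads' must be a single non-negative integer")
  }
  nReads <- as.integer(nReads)
  if (!is.numeric(scoreLaw) || length(scoreLaw) != .QS_MAX + 1L ||
      any(scoreLaw < 0) || abs(sum(scoreLaw) - 1) > 1e-8) {
    qs_usage_error("'scoreLaw' must be 94 non-negative probabilities summing to 1")
  }
  h <- as.integer(h)
  d <- as.integer(d)
  emptyTruth <- data.frame(
    read = integer(0), start = integer(0), end = integer(0), kind = character(0)
  )
  if (nReads == 0L) {
    return(list(reads = FastqReads(), truth = emptyTruth))
  }

  planBy <- vector("list", nReads)
  if (!is.null(repeatPlan) && nrow(repeatPlan) > 0L) {
    plan <- .validRepeatPlan(repeatPlan)
    if (any(plan$read < 1L | plan$read > nReads)) {
      qs_usage_error("'repeatPlan$read' indices must lie in 1..nReads")
    }
    bad <- which(!(
      (plan$kind == "homopolymer" & nchar(plan$unit) == 1L & plan$copies >= h) |
        (plan$kind == "dinucleotide" & nchar(plan$unit) == 2L &
           substr(plan$unit, 1L, 1L) != substr(plan$unit, 2L, 2L) & plan$copies >= d)
    ))
    if (length(bad)) {
      qs_usage_error(sprintf(
        "repeatPlan row %d: kind '%s' with unit '%s' and %d copies is not a detectable repeat (h = %d, d = %d)",
        bad[1L], plan$kind[bad[1L]], plan$unit[bad[1L]], plan$copies[bad[1L]], h, d
      ))
    }
    for (i in seq_len(nrow(plan))) {
      r <- plan$read[i]
      planBy[[r]] <- rbind(planBy[[r]], plan[i, , drop = FALSE])
    }
  }

  withSeed(seed, {
    lengths <- pmax(1L, rnbinom(nReads, size = dispersion, mu = meanLength))
    sequences <- character(nReads)
    truthList <- vector("list", nReads)
    for (r in seq_len(nReads)) {
      plants <- planBy[[r]]
      if (!is.null(plants)) {
        plants$copies <- as.integer(plants$copies)
        widths <- as.integer(nchar(plants$unit)) * plants$copies
        lengths[r] <- max(lengths[r], max(widths)) # plants must fit
        # clamp plant positions into the read, then check disjointness
        plants$pos <- pmin(pmax(as.integer(plants$pos), 0L), lengths[r] - widths)
        iv <- data.frame(start = plants$pos, end = plants$pos + widths)
        o <- order(iv$start)
        iv <- iv[o, , drop = FALSE]
        plants <- plants[o, , drop = FALSE]
        if (nrow(iv) > 1L && any(iv$start[-1L] < iv$end[-nrow(iv)])) {
          qs_usage_error(sprintf("repeatPlan: overlapping planted repeats in read %d", r))
        }
        truth <- data.frame(
          read = r, start = as.integer(iv$start), end = as.integer(iv$end),
          kind = plants$kind
        )
      } else {
        truth <- emptyTruth
      }
      n <- lengths[r]
      ok <- FALSE
      for (attempt in seq_len(maxAttempts)) {
        codes <- .BASE_CODES[sample.int(4L, n, replace = TRUE)]
        if (!is.null(plants)) {
          for (i in seq_len(nrow(plants))) {
            unitCodes <- utf8ToInt(toupper(plants$unit[i]))
            span <- plants$pos[i] + seq_len(nchar(plants$unit[i]) * plants$copies[i])
            codes[span] <- rep.int(unitCodes, plants$copies[i])
          }
        }
        sq <- intToUtf8(codes)
        if (.truthMatches(sq, h, d, truth)) {
          sequences[r] <- sq
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        qs_data_error(sprintf(
          "could not generate a read of length %d matching its repeat ground truth in %d attempts; shorten reads or relax h/d",
          n, maxAttempts
        ))
      }
      truthList[[r]] <- truth
    }
    scores <- sample.int(.QS_MAX + 1L, sum(lengths), replace = TRUE, prob = scoreLaw) - 1L
    quality <- character(nReads)
    at <- 0L
    for (r in seq_len(nReads)) {
      quality[r] <- intToUtf8(scores[at + seq_len(lengths[r])] + .QS_OFFSET)
      at <- at + lengths[r]
    }
    truth <- do.call(rbind, c(list(emptyTruth), truthList))
    rownames(truth) <- NULL
    list(
      reads = new("FastqReads",
        header = sprintf("sim_read_%d", seq_len(nReads)),
        sequence = sequences,
        separator = rep("", nReads),
        quality = quality
      ),
      truth = truth
    )
  })
}

#' Write repeat ground truth as a BED-like annotation table
#'
#' Four tab-separated columns without header: read identifier, start, end
#' (0-based, half-open) and repeat kind.
#'
#' @param sim Result of [simulateFastq()].
#' @param path Output file path.
#' @return Invisibly, the number of annotation rows written.
#' @export
writeRepeatAnnotations <- function(sim, path) {
  truth <- sim$truth
  out <- data.frame(
    id = readHeaders(sim$reads)[truth$read],
    start = truth$start, end = truth$end, kind = truth$kind
  )
  write.table(out, path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(nrow(out))
}
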
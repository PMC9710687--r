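# Repeat detection and the two-regime context quantizer, checked against
# brute-force oracles that test substrings against the literal definitions.

test_that("homopolymer detection matches its published examples", {
  expect_identical(findHomopolymerRuns("AAAAA", 5)$start, 0L)
  expect_identical(findHomopolymerRuns("AAAAA", 5)$end, 5L)
  hp <- findHomopolymerRuns("AAAACCCCC", 5)
  expect_identical(hp$start, 4L)
  expect_identical(hp$end, 9L)
  expect_identical(nrow(findHomopolymerRuns("ACGTACGT", 5)), 0L)
  # case-insensitive; N participates like any letter
  expect_identical(findHomopolymerRuns("aAaAa", 2)$end, 5L)
  expect_identical(findHomopolymerRuns("NNNNN", 5)$end, 5L)
  expect_identical(nrow(findHomopolymerRuns("", 5)), 0L)
})

test_that("dinucleotide detection matches its published examples", {
  dv <- findDinucleotideRepeats("ACACACAC", 4)
  expect_identical(dv$start, 0L)
  expect_identical(dv$end, 8L)
  expect_identical(nrow(findDinucleotideRepeats("ACACAC", 4)), 0L)
  dv <- findDinucleotideRepeats("TACACACACG", 4)
  expect_identical(dv$start, 1L)
  expect_identical(dv$end, 9L)
  # equal-letter units are homopolymer territory, not dinucleotide repeats
  expect_identical(nrow(findDinucleotideRepeats(strrep("A", 20), 4)), 0L)
})

test_that("repeat masks match their published examples", {
  expect_true(all(repeatMask("CCCCC", h = 5, d = 4, delta = 5)))
  expect_false(any(repeatMask("ACGT", h = 5, d = 4, delta = 5)))
  # 20-base read with one repeat at [8, 13): flagged positions exactly 3..17
  sq <- paste0("ACGTACGT", "CCCCC", "GTACGTA")
  expect_identical(which(repeatMask(sq, h = 5, d = 4, delta = 5)) - 1L, 3:17)
})

test_that("detection and masks equal the brute-force oracle on random
           and planted sequences", {
  set.seed(1003)
  nCases <- 400L
  for (i in seq_len(nCases)) {
    n <- sample(1:150, 1L)
    sq <- randomSequence(n)
    h <- sample(2:6, 1L)
    d <- sample(2:5, 1L)
    delta <- sample(0:8, 1L)

    hp <- findHomopolymerRuns(sq, h)
    ohp <- oracleHomopolymers(sq, h)
    expect_identical(hp$start, ohp$start, label = sq)
    expect_identical(hp$end, ohp$end, label = sq)

    dn <- findDinucleotideRepeats(sq, d)
    odn <- oracleDinucleotide(sq, d)
    expect_identical(dn$start, odn$start, label = sq)
    expect_identical(dn$end, odn$end, label = sq)

    expect_identical(repeatMask(sq, h, d, delta), oracleMask(sq, h, d, delta),
                     label = sq)
  }
  # planted fixtures with known ground truth
  plan <- data.frame(
    read = 1:4,
    kind = c("homopolymer", "dinucleotide", "homopolymer", "dinucleotide"),
    unit = c("T", "AC", "N", "GT"),
    copies = c(6L, 5L, 7L, 4L),
    pos = c(3L, 12L, 0L, 30L)
  )
  sim <- simulateFastq(nReads = 4, meanLength = 60, repeatPlan = plan, seed = 55)
  for (r in 1:4) {
    sq <- readSequences(sim$reads)[r]
    truth <- sim$truth[sim$truth$read == r, ]
    found <- repeatIntervals(sq, h = 5, d = 4)
    expect_identical(found$start, truth$start)
    expect_identical(found$end, truth$end)
    expect_identical(repeatMask(sq, 5, 4, 3), oracleMask(sq, 5, 4, 3))
  }
})

test_that("mask grows monotonically with delta and saturates degenerately", {
  set.seed(2027)
  for (i in 1:50) {
    sq <- randomSequence(sample(10:120, 1L), alphabet = c("A", "C", "G", "T"))
    m0 <- repeatMask(sq, 5, 4, delta = 0)
    m2 <- repeatMask(sq, 5, 4, delta = 2)
    m9 <- repeatMask(sq, 5, 4, delta = 9)
    expect_true(all(m2[m0]))  # mask(delta1) subset of mask(delta2)
    expect_true(all(m9[m2]))
    # delta >= read length: all-true whenever any repeat exists
    mBig <- repeatMask(sq, 5, 4, delta = nchar(sq))
    if (any(m0)) expect_true(all(mBig)) else expect_false(any(mBig))
  }
})

test_that("context quantizer applies far/near by regime", {
  cq <- ContextQuantizer(far = "F:10", near = "Q8", delta = 5)
  expect_s4_class(cq, "ContextQuantizer")

  # repeat-free read: identical to applying the far quantizer alone
  clean <- FastqReads("r", "ACGTACGTACGT", "", list(seq(0L, 88L, by = 8L)))
  expect_identical(
    qualityStrings(quantizeReads(cq, clean)),
    qualityStrings(quantizeReads(builtinQuantizer("F10"), clean))
  )
  # all-repeat read: identical to applying the near quantizer alone
  homo <- FastqReads("r", strrep("G", 12), "", list(seq(0L, 88L, by = 8L)))
  expect_identical(
    qualityStrings(quantizeReads(cq, homo)),
    qualityStrings(quantizeReads(builtinQuantizer("Q8"), homo))
  )

  # planted dinucleotide repeat: near regime exactly delta positions around
  # the ground-truth interval, far elsewhere
  sim <- simulateFastq(
    nReads = 1, meanLength = 40,
    repeatPlan = data.frame(read = 1, kind = "dinucleotide", unit = "AC",
                            copies = 4, pos = 10),
    seed = 12
  )
  reads <- sim$reads[1]
  cq28 <- ContextQuantizer(far = "Q2", near = "Q8", delta = 5)
  out <- qualityScores(quantizeReads(cq28, reads))[[1]]
  s <- qualityScores(reads)[[1]]
  near <- seq_along(s) - 1L >= sim$truth$start[1] - 5L &
    seq_along(s) - 1L <= sim$truth$end[1] - 1L + 5L
  expect_identical(out[near], quantizeScores(builtinQuantizer("Q8"), s[near]))
  expect_identical(out[!near], quantizeScores(builtinQuantizer("Q2"), s[!near]))

  # bases, headers, separators unchanged; record invariants still hold
  expect_identical(readSequences(out <- quantizeReads(cq, sim$reads)),
                   readSequences(sim$reads))
  expect_true(validObject(out))
})

test_that("context quantizer equals far quantizer when no repeats exist", {
  set.seed(31)
  cq <- ContextQuantizer(far = "Q4", near = "Q8", delta = 5)
  for (i in 1:20) {
    repeat {
      sq <- randomSequence(sample(1:80, 1L), alphabet = c("A", "C", "G", "T"))
      if (nrow(repeatIntervals(sq, 5, 4)) == 0L) break
    }
    reads <- FastqReads("r", sq, "", list(sample(0:93, nchar(sq), replace = TRUE)))
    expect_identical(
      qualityStrings(quantizeReads(cq, reads)),
      qualityStrings(quantizeReads(builtinQuantizer("Q4"), reads))
    )
  }
})

test_that("ContextQuantizer validates its parameters", {
  expect_error(ContextQuantizer("F:10", "Q8", h = 1), "h")
  expect_error(ContextQuantizer("F:10", "Q8", d = 0), "d")
  expect_error(ContextQuantizer("F:10", "Q8", delta = -1), "delta")
  cq <- ContextQuantizer("F:10", "Q8")
  expect_identical(cq@h, 5L)
  expect_identical(cq@d, 4L)
  expect_identical(cq@delta, 5L)
})
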
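# Phred+33 codec, 4-line FASTQ round trips, gzip transparency, downsampling.

test_that("decodeQuality maps ASCII 33..126 to scores 0..93", {
  expect_identical(decodeQuality("!"), 0L)
  expect_identical(decodeQuality("~"), 93L)
  expect_identical(decodeQuality("+5?"), c(10L, 20L, 30L))
  expect_identical(decodeQuality(""), integer(0))
})

test_that("encodeQuality is the exact inverse of decodeQuality", {
  expect_identical(encodeQuality(0L), "!")
  expect_identical(encodeQuality(93L), "~")
  expect_identical(encodeQuality(c(10L, 10L, 10L)), "+++")
  expect_identical(decodeQuality(encodeQuality(0:93)), 0:93)
  set.seed(41)
  for (i in 1:20) {
    s <- sample(0:93, sample.int(200, 1L), replace = TRUE)
    expect_identical(decodeQuality(encodeQuality(s)), s)
  }
  # and encode(decode(.)) is identity on valid quality strings
  qual <- encodeQuality(sample(0:93, 100, replace = TRUE))
  expect_identical(encodeQuality(decodeQuality(qual)), qual)
})

test_that("out-of-range scores and characters are hard errors with positions", {
  expect_error(encodeQuality(c(5L, 94L)), "position 2")
  expect_error(encodeQuality(-1L), "position 1")
  expect_error(decodeQuality("II\nI"), "position 3")
  expect_error(decodeQuality(intToUtf8(c(70L, 20L))), "ASCII 20")
})

test_that("FastqReads enforces its invariants", {
  expect_error(FastqReads("r", "ACGT", "", "II"), "length")
  expect_error(FastqReads("r\nx", "AC", "", "II"), "line break")
  expect_silent(FastqReads("r", "", "", ""))
})

test_that("read/write round trip preserves every field and byte", {
  reads <- FastqReads(
    header = c("read1 ch=22", "read2", "read3"),
    sequence = c("ACGTN", "", "acgtacgt"),
    separator = c("", "read2", ""),
    quality = list(c(0L, 93L, 10L, 20L, 30L), integer(0), rep(40L, 8L))
  )
  path <- writeTempFastq(reads)
  back <- readFastq(path)
  expect_identical(readHeaders(back), readHeaders(reads))
  expect_identical(readSequences(back), readSequences(reads))
  expect_identical(readSeparators(back), readSeparators(reads))
  expect_identical(qualityStrings(back), qualityStrings(reads))

  # parse-then-write of a 4-line file is byte identical
  path2 <- tempfile(fileext = ".fastq")
  writeFastq(back, path2)
  expect_identical(readBin(path, "raw", file.size(path)),
                   readBin(path2, "raw", file.size(path2)))
})

test_that("gzip input is detected by magic bytes and round trips", {
  reads <- FastqReads(
    c("a", "b", "c"), c("ACGT", "GGGG", "TTAA"), rep("", 3),
    list(rep(10L, 4), rep(20L, 4), rep(30L, 4))
  )
  gzPath <- writeTempFastq(reads, gz = TRUE)
  expect_identical(qualityStrings(readFastq(gzPath)), qualityStrings(reads))
  # renamed gzip file (no .gz extension) still decompresses
  renamed <- tempfile(fileext = ".fastq")
  file.copy(gzPath, renamed)
  expect_identical(readSequences(readFastq(renamed)), readSequences(reads))
})

test_that("empty inputs give empty outputs", {
  path <- tempfile(fileext = ".fastq")
  expect_identical(writeFastq(FastqReads(), path), 0L)
  expect_identical(file.size(path), 0)
  expect_identical(length(readFastq(path)), 0L)
})

test_that("malformed FASTQ aborts with the offending record ordinal", {
  path <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGTG", "+", "IIII"), path)
  expect_error(readFastq(path), "record 2.*length", class = "qsquant_data_error")

  writeLines(c("@r1", "ACGT", "+", "IIII", "r2", "ACGT", "+", "IIII"), path)
  expect_error(readFastq(path), "record 2.*'@'")

  writeLines(c("@r1", "ACGT", "-", "IIII"), path)
  expect_error(readFastq(path), "record 1.*'\\+'")

  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT"), path)
  expect_error(readFastq(path), "truncated", class = "qsquant_data_error")

  writeLines(c("@r1", "ACGT", "+", paste0("II", intToUtf8(20L), "I")), path)
  expect_error(readFastq(path), "record 1.*position 3")
})

test_that("streamFastq visits all records in order with bounded chunks", {
  sim <- simulateFastq(nReads = 123, meanLength = 60, seed = 5)
  path <- writeTempFastq(sim$reads)
  chunks <- list()
  total <- streamFastq(path, function(chunk) {
    chunks[[length(chunks) + 1L]] <<- chunk
  }, chunkSize = 25L)
  expect_identical(total, 123L)
  expect_identical(length(chunks), 5L) # 4 x 25 + 23
  expect_true(all(vapply(chunks[1:4], length, integer(1)) == 25L))
  merged <- do.call(c, chunks)
  expect_identical(readHeaders(merged), readHeaders(sim$reads))
  expect_identical(qualityStrings(merged), qualityStrings(sim$reads))
})

test_that("downsampling selects an exact half-up count, order-preserved", {
  sim <- simulateFastq(nReads = 10, meanLength = 40, seed = 9)
  kept <- downsampleReads(sim$reads, 0.5, seed = 101)
  expect_identical(length(kept), 5L)
  # identical seed => identical selection
  again <- downsampleReads(sim$reads, 0.5, seed = 101)
  expect_identical(readHeaders(kept), readHeaders(again))
  # subsequence of the input, original order
  pos <- match(readHeaders(kept), readHeaders(sim$reads))
  expect_false(is.unsorted(pos, strictly = TRUE))

  expect_identical(length(downsampleReads(sim$reads, 0, seed = 1)), 0L)
  expect_identical(readHeaders(downsampleReads(sim$reads, 1, seed = 1)),
                   readHeaders(sim$reads))
  # half-up tie: 25 reads at 10% -> 2.5 -> 3
  sim25 <- simulateFastq(nReads = 25, meanLength = 30, seed = 2)
  expect_identical(length(downsampleReads(sim25$reads, 0.1, seed = 7)), 3L)
  expect_error(downsampleReads(sim$reads, 1.2, seed = 1), "fraction")
})

test_that("downsampling does not disturb the caller's RNG stream", {
  set.seed(77)
  before <- .Random.seed
  invisible(downsampleReads(simulateFastq(nReads = 6, meanLength = 30, seed = 1)$reads,
                            0.5, seed = 3))
  expect_identical(.Random.seed, before)
})
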
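test_that("3' trimming shortens reads, drops too-short reads, and counts them", {
  set.seed(301)
  x <- make_reads(c(random_seq(300), random_seq(10)))
  y <- trimReads3p(x, 20)
  expect_equal(length(y), 1L)
  expect_equal(unname(Biostrings::width(readSequences(y))), 280L)
  log <- processLog(y)
  expect_equal(log$input[log$stage == "trim_3prime"], 2L)
  expect_equal(log$discarded[log$stage == "trim_3prime"], 1L)
  ## qualities are trimmed in lock-step
  expect_equal(unname(nchar(as.character(readQualities(y)))), 280L)
  ## n = 0 is the identity on sequences
  z <- trimReads3p(x, 0)
  expect_identical(as.character(readSequences(z)),
                   as.character(readSequences(x)))
  expect_error(trimReads3p(x, -1), "non-negative")
})

test_that("quality filtering applies the mean-Phred rule and the min mode", {
  mk <- function(q) paste(rawToChar(as.raw(q + 33L)), collapse = "")
  seqs <- rep(strrep("A", 10), 3)
  quals <- c(mk(rep(30, 10)),            # mean 30 -> kept
             mk(rep(10, 10)),            # mean 10 -> removed
             mk(c(rep(22, 9), 1)))       # mean 19.9 -> removed at Q20
  x <- make_reads(seqs, quals)
  y <- filterByQuality(x, 20, mode = "mean")
  expect_equal(length(y), 1L)
  log <- processLog(y)
  expect_equal(log$passed[log$stage == "quality_filter"], 1L)
  ## min mode: a single base below threshold removes the read
  ymin <- filterByQuality(x, 20, mode = "min")
  expect_equal(length(ymin), 1L)
  x30 <- make_reads(seqs[1], quals[1])
  expect_equal(length(filterByQuality(x30, 20, mode = "min")), 1L)
  ## filtering is idempotent
  y2 <- filterByQuality(y, 20)
  expect_identical(as.character(readSequences(y2)),
                   as.character(readSequences(y)))
  ## reads without qualities are an error
  noq <- AmpliconReadSet(Biostrings::DNAStringSet(c(r1 = "ACGT")), "s1")
  expect_error(filterByQuality(noq, 20), "no quality scores")
})

test_that("length normalization keeps the inner window and discards short reads", {
  set.seed(302)
  long <- random_seq(360)
  exact <- random_seq(320)
  short <- random_seq(300)
  x <- make_reads(c(long, exact, short))
  pm <- makePositionalMatrix(x, endTrim = 10, targetLength = 320)
  expect_s4_class(pm, "PositionalMatrix")
  expect_equal(length(pm), 1L)   # only the 360-nt read survives
  expect_equal(matrixWidth(pm), 320L)
  ## the surviving window is bases 11..330 of the original read
  expect_identical(as.character(readSequences(pm)[[1]]),
                   substr(long, 11, 330))
  ## with no end trim an exact-length read passes unchanged
  pm0 <- makePositionalMatrix(make_reads(exact), endTrim = 0,
                              targetLength = 320)
  expect_identical(as.character(readSequences(pm0)[[1]]), exact)
  log <- processLog(pm)
  expect_equal(log$discarded[log$stage == "length_normalization"], 2L)
  expect_error(makePositionalMatrix(x, targetLength = 0), "positive")
})

test_that("dereplication merges identical reads, sorts by abundance with lexicographic ties", {
  pm <- make_pm(c("AAA", "AAC", "AAA", "AAA"),
                sample = c("s1", "s1", "s2", "s2"))
  u <- dereplicate(pm)
  expect_identical(as.character(readSequences(u)), c("AAA", "AAC"))
  expect_equal(totalCounts(u), c(3L, 1L))
  expect_equal(unname(sampleCounts(u)[1, "s1"]), 1L)
  expect_equal(unname(sampleCounts(u)[1, "s2"]), 2L)
  ## tie-break: equal counts -> lexicographic order (brute-force sort oracle)
  pm2 <- make_pm(c("AAC", "AAC", "AAA", "AAA"))
  u2 <- dereplicate(pm2)
  seqs <- c("AAC", "AAC", "AAA", "AAA")
  tab <- table(seqs)
  oracle <- names(tab)[order(-as.integer(tab), names(tab))]
  expect_identical(as.character(readSequences(u2)), oracle)
  ## all identical -> one unique
  u3 <- dereplicate(make_pm(rep("ACGT", 5)))
  expect_equal(length(u3), 1L)
  expect_equal(totalCounts(u3), 5L)
})

test_that("dereplication conserves the read multiset", {
  set.seed(303)
  seqs <- sample(vapply(1:6, function(i) random_seq(8), ""), 40,
                 replace = TRUE)
  samples <- sample(c("s1", "s2", "s3"), 40, replace = TRUE)
  u <- dereplicate(make_pm(seqs, sample = samples))
  expect_equal(sum(sampleCounts(u)), 40L)
  ## expanding uniques by their counts recovers the input multiset
  expanded <- rep(as.character(readSequences(u)), totalCounts(u))
  expect_identical(sort(expanded), sort(seqs))
  ## per-sample counts match a direct tabulation
  for (s in c("s1", "s2", "s3")) {
    direct <- table(factor(seqs[samples == s],
                           levels = as.character(readSequences(u))))
    expect_equal(unname(sampleCounts(u)[, s]), unname(as.integer(direct)))
  }
})

test_that("stage counts telescope: input = passed + discarded at every stage", {
  set.seed(304)
  seqs <- vapply(sample(330:370, 30, TRUE), random_seq, "")
  quals <- vapply(nchar(seqs), function(n)
    paste(rawToChar(as.raw(sample(c(5:15, 30:40), n, TRUE) + 33L)),
          collapse = ""), "")
  x <- make_reads(seqs, quals)
  pm <- makePositionalMatrix(
    filterByQuality(trimReads3p(x, 20), 20), 10, 320)
  log <- processLog(pm)
  expect_equal(log$input, log$passed + log$discarded)
  ## stages chain: output of one stage is input of the next
  expect_equal(log$input[-1], log$passed[-length(log$passed)])
})
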
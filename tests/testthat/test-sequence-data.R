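test_that("alphabets enforce their invariants and provide built-ins", {
  expect_equal(alphabetSize(builtinAlphabet("dna")), 4L)
  expect_equal(alphabetSize(builtinAlphabet("rna")), 4L)
  expect_equal(alphabetSize(builtinAlphabet("protein")), 20L)
  expect_equal(alphabetSize(builtinAlphabet("protein*")), 21L)
  expect_true("*" %in% alphabetCharacters(builtinAlphabet("protein*")))
  expect_error(Alphabet("A"), "at least 2")
  expect_error(Alphabet(c("A", "A", "B")), "unique")
  custom <- Alphabet(c("0", "1"), name = "binary")
  expect_equal(alphabetSize(custom), 2L)
})

test_that("one-hot encoding places indicators as defined", {
  x <- oneHotEncode("A", dnaAlph)
  expect_equal(as.vector(x), c(1L, 0L, 0L, 0L))
  x3 <- oneHotEncode("ACG", dnaAlph)
  expect_equal(sum(x3), 3)
  expect_equal(which(x3 == 1L), c(1L, 6L, 11L))  # (0,A), (1,C), (2,G)
  # one character per position: row sums are L, per-position blocks sum 1
  set.seed(1)
  seqs <- randomSequences(20, 7, dnaAlph)
  X <- oneHotEncode(seqs, dnaAlph)
  expect_true(all(rowSums(X) == 7))
  for (l in 0:6)
    expect_true(all(rowSums(X[, l * 4 + 1:4]) == 1))
  # case normalization, no silent U/T conversion
  expect_equal(oneHotEncode("acgt", dnaAlph), oneHotEncode("ACGT", dnaAlph))
  expect_error(oneHotEncode("ACGU", dnaAlph), "'U'")
  expect_error(oneHotEncode(c("ACG", "AC"), dnaAlph), "unequal lengths")
})

test_that("pairwise features cover exactly the l' > l pairs", {
  x <- oneHotEncode("AT", dnaAlph)
  pf <- pairwiseFeatures(x)
  expect_equal(sum(pf), 1)
  expect_equal(colnames(pf)[which(pf == 1L)], "0:A,1:T")
  x3 <- oneHotEncode("ACG", dnaAlph)
  expect_equal(sum(pairwiseFeatures(x3)), 3)  # 3 choose 2
  # no l' <= l feature exists in the naming
  nm <- colnames(pairwiseFeatures(x3))
  pos <- t(vapply(strsplit(nm, "[:,]"), function(s)
    as.integer(c(s[1], s[3])), integer(2)))
  expect_true(all(pos[, 2] > pos[, 1]))
  # neighbor restriction
  nf <- pairwiseFeatures(x3, neighborOnly = TRUE)
  expect_equal(ncol(nf), 2 * 16)
  expect_equal(sum(nf), 2)
  # empty for L = 1
  expect_equal(ncol(pairwiseFeatures(oneHotEncode("A", dnaAlph))), 0)
})

test_that("log2 enrichment follows the pseudocounted ratio", {
  expect_equal(log2Enrichment(3, 3, 3, 3), 0)
  expect_equal(log2Enrichment(3, 7, 3, 3), 1.0)
  expect_equal(log2Enrichment(0, 0, 0, 0), 0)  # pseudocounts cancel
  expect_equal(log2Enrichment(c(3, 0), c(7, 0), 3, 3),
               c(1, log2((1 / 4) / (1 / 4))))
  expect_error(log2Enrichment(-1, 0, 0, 0), "nonnegative")
  expect_error(log2Enrichment(1.5, 0, 0, 0), "nonnegative integers")
})

test_that("log10 PSI puts the consensus at PSI = 100", {
  r <- log10Psi(9, 9, 9, 9)
  expect_equal(r$y, 2)
  expect_equal(r$psi, 100)
  r2 <- log10Psi(0, 9, 9, 9)
  expect_equal(r2$y, 1.0)
  expect_equal(r2$psi, 10)
  # PSI = 10^y definitionally
  r3 <- log10Psi(c(2, 5, 17), c(8, 11, 20), 9, 9)
  expect_equal(r3$psi, 10^r3$y)
})

test_that("count filtering preserves order, subsets, and is idempotent", {
  df <- data.frame(seq = c("AA", "CC", "GG"), c_in = c(3, 10, 12))
  expect_message(kept <- filterByMinCount(df, "c_in", 10), "2/3")
  expect_equal(kept$seq, c("CC", "GG"))
  expect_message(id <- filterByMinCount(df, "c_in", 0), "3/3")
  expect_equal(id, df)
  suppressMessages(
    expect_equal(filterByMinCount(kept, "c_in", 10), kept))  # idempotent
  expect_error(suppressMessages(filterByMinCount(df, "nope", 1)),
               "not found")
  # MaveDataset counts mode
  d <- MaveDataset(c("AC", "GT", "CA"),
                   counts = rbind(c(5, 6), c(1, 2), c(9, 9)))
  suppressMessages(f <- filterByMinCount(d, "total", 10))
  expect_equal(sequences(f), c("AC", "CA"))
})

test_that("dataset validity enforces one mode and clean inputs", {
  expect_error(MaveDataset("ACGT"), "exactly one")
  expect_error(MaveDataset("ACGT", y = 1, bins = 0L), "exactly one")
  expect_error(MaveDataset(c("AC", "ACG"), y = c(1, 2)), "unequal")
  expect_error(MaveDataset("AC", counts = rbind(c(0, 0))), "total >= 1")
  expect_error(MaveDataset("AC", counts = rbind(c(-1, 2))), "nonnegative")
  expect_error(MaveDataset(c("AC", "GT"), y = c(1, 2), se = c(1, -1)),
               "positive")
  d <- MaveDataset(c("AC", "GT"), y = c(1, 2), se = c(0.1, 0.2))
  expect_equal(datasetMode(d), "ge")
  expect_equal(nObs(d), 2L)
  expect_equal(measurements(d[2]), 2)
})

test_that("TSV round trips preserve datasets and reject malformed files", {
  tmp <- tempfile(fileext = ".tsv")
  d <- MaveDataset(c("ACGT", "AAGT"), y = c(0.5, -1.25),
                   se = c(0.1, 0.2))
  writeMaveDataset(d, tmp)
  r <- readMaveDataset(tmp)
  expect_equal(sequences(r), sequences(d))
  expect_equal(measurements(r), measurements(d))
  expect_equal(measurementSE(r), measurementSE(d))
  dc <- MaveDataset(c("ACGT", "AAGT"),
                    counts = rbind(c(3, 0, 1), c(2, 2, 2)))
  writeMaveDataset(dc, tmp)
  rc <- readMaveDataset(tmp)
  expect_equal(binCounts(rc), binCounts(dc), ignore_attr = TRUE)
  # ragged sequences named by row; negative counts rejected
  writeLines(c("seq\ty", "ACGTA\t1", "ACGT\t2"), tmp)
  expect_error(readMaveDataset(tmp), "row")
  writeLines(c("seq\tct_0\tct_1", "ACGT\t-1\t3"), tmp)
  expect_error(readMaveDataset(tmp), "nonnegative|counts")
})
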
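test_that("FASTA alignments are read and coded correctly", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "AC-", ">b", "AC-"), f)
  aln <- read_alignment(f, "fasta")
  expect_equal(dim(aln$codes), c(2L, 3L))
  expect_identical(aln$codes[1, ], aln$codes[2, ])
  expect_equal(aln$codes[1, ], c(1L, 2L, 21L))  # A, C, gap(last)
  expect_equal(aln$ids, c("a", "b"))
  # unknown letters map to the gap by default, error on request
  writeLines(c(">a", "AXC"), f)
  expect_equal(read_alignment(f, "fasta")$codes[1, 2], 21L)
  expect_error(read_alignment(f, "fasta", unknown = "error"), "X")
  # ragged input is a format error
  writeLines(c(">a", "ACD", ">b", "AC"), f)
  expect_error(read_alignment(f, "fasta"), "ragged")
  # empty file is an empty-input error
  writeLines(character(0), f)
  expect_error(read_alignment(f, "fasta"), "empty")
})

test_that("Stockholm insert columns are dropped before coding", {
  f <- withr::local_tempfile(fileext = ".sto")
  writeLines(c("# STOCKHOLM 1.0",
               "#=GF ID test",
               "seq1 AC.Dx.E",
               "seq2 ACaD..E",
               "#=GC RF   xx.x..x",
               "//"), f)
  aln <- read_alignment(f, "stockholm")
  # columns 3 ('.'/insert), 5 (lowercase) and 6 ('.') are inserts
  expect_equal(ncol(aln$codes), 4L)
  expect_equal(decode_sequences(aln$codes, aln$alphabet), c("ACDE", "ACDE"))
})

test_that("encoding round-trips every alphabet symbol", {
  seq <- paste(aa_alphabet(), collapse = "")
  codes <- encode_sequences(seq)
  expect_equal(as.vector(codes), 1:21)
  expect_equal(decode_sequences(codes), seq)
})

test_that("preprocessing removes masked columns and duplicates, idempotently", {
  codes <- rbind(c(1L, 2L, 3L, 4L), c(1L, 2L, 3L, 4L), c(2L, 2L, 3L, 4L))
  aln <- codes_alignment(codes, c("A", "B", "C", "-"))
  pp <- preprocess_alignment(aln)
  expect_equal(nrow(pp$codes), 2L)          # duplicate removed, first kept
  expect_equal(pp$ids, c("1", "3"))
  pp2 <- preprocess_alignment(pp)
  expect_identical(pp2$codes, pp$codes)     # idempotent
  # match-column mask drops flagged columns
  ppm <- preprocess_alignment(aln, match_columns = c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(ncol(ppm$codes), 3L)
  expect_error(preprocess_alignment(aln, match_columns = c(TRUE, FALSE)),
               "mask length")
})

test_that("sequence reweighting follows the strict >90% identity rule", {
  # B identical copies: every weight 1/B, effective sample size 1
  dup <- codes_alignment(matrix(1L, 5, 10), aa_alphabet())
  w <- compute_sequence_weights(dup)
  expect_equal(unname(w), rep(1 / 5, 5))
  expect_equal(sum(w), 1)
  # all pairwise identities below threshold: all weights 1
  set.seed(3)
  div <- codes_alignment(matrix(sample.int(21L, 4 * 20, replace = TRUE), 4, 20),
                         aa_alphabet())
  expect_equal(unname(compute_sequence_weights(div)), rep(1, 4))
  # 3 sequences, seqs 1-2 share 19/20 = 95% identity, seq 3 unrelated:
  # brute-force pairwise counting gives weights (1/2, 1/2, 1)
  s1 <- rep(1L, 20); s2 <- s1; s2[20] <- 2L; s3 <- rep(3:4, 10)
  trio <- codes_alignment(rbind(s1, s2, s3), aa_alphabet())
  expect_equal(unname(compute_sequence_weights(trio)), c(0.5, 0.5, 1))
  # strictness: exactly 90% identity is NOT a neighbor
  s4 <- s1; s4[1:2] <- 2L  # 18/20 = 90%
  duo <- codes_alignment(rbind(s1, s4), aa_alphabet())
  expect_equal(unname(compute_sequence_weights(duo, 0.9)), c(1, 1))
  # threshold 1.0 after dedup gives all weights 1
  expect_equal(unname(compute_sequence_weights(trio, 1.0)), c(1, 1, 1))
  expect_error(compute_sequence_weights(trio, 0), "identity_threshold")
  expect_error(compute_sequence_weights(trio, 1.5), "identity_threshold")
})

test_that("weighted averages implement the reweighted MSA mean", {
  expect_equal(weighted_average(c(1, 2, 3), rep(1, 3)), 2)
  expect_equal(weighted_average(c(0, 0, 3), c(0.5, 0.5, 1)), 1.5)
  expect_equal(weighted_average(5, 0.3), 5)
  expect_error(weighted_average(c(1, 2), c(0, 0)), "zero")
  expect_error(weighted_average(c(1, 2), 1), "length")
})

test_that("train/test splits are disjoint, seeded, and reweighted on train", {
  set.seed(99)
  aln <- codes_alignment(matrix(sample.int(4L, 10 * 12, replace = TRUE), 10, 12),
                         c("A", "B", "C", "-"))
  sp <- train_test_split(aln, 0.2, seed = 5)
  expect_equal(nrow(sp$train$codes), 8L)
  expect_equal(nrow(sp$test$codes), 2L)
  expect_length(intersect(sp$train$ids, sp$test$ids), 0L)
  expect_length(sp$train_weights, 8L)
  sp2 <- train_test_split(aln, 0.2, seed = 5)
  expect_identical(sp$test$ids, sp2$test$ids)
  # different seeds give different partitions with high probability
  parts <- vapply(1:100, function(s) {
    paste(train_test_split(aln, 0.2, seed = s, weights = FALSE)$test$ids,
          collapse = ",")
  }, character(1))
  expect_gt(length(unique(parts)), 10L)
  expect_error(train_test_split(aln, 1.2), "test_fraction")
})

test_that("alignments and weights round-trip through their file formats", {
  set.seed(1)
  aln <- codes_alignment(matrix(sample.int(21L, 3 * 8, replace = TRUE), 3, 8),
                         aa_alphabet())
  f <- withr::local_tempfile(fileext = ".fasta")
  write_alignment(aln, f)
  back <- read_alignment(f, "fasta")
  expect_identical(back$codes, aln$codes)
  w <- compute_sequence_weights(aln)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_sequence_weights(w, tf)
  tab <- utils::read.delim(tf)
  expect_equal(tab$weight, unname(w))
})
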
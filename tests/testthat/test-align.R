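test_that("local alignment reproduces worked examples", {
  a <- local_align("ACGT", "ACGT")
  expect_equal(a$score, 4)
  expect_equal(a$query_span, c(0, 4))
  expect_equal(a$target_span, c(0, 4))

  # one internal mismatch beats the shorter exact suffix match
  expect_equal(local_align("ACGTACGT", "ACGAACGT")$score, 6)
  # 7 matches minus a length-1 gap costing 1 + 1
  expect_equal(local_align("ACGTTACG", "ACGTACG")$score, 5)

  z <- local_align("AAAA", "CCCC")
  expect_equal(z$score, 0)
  expect_equal(z$query_span, c(0, 0))

  expect_error(local_align("", "ACGT"), "non-empty")
})

test_that("full DP matches the brute-force oracle exactly on random pairs", {
  set.seed(101)
  for (i in 1:200) {
    q <- rand_seq(sample(1:40, 1))
    t <- rand_seq(sample(1:40, 1))
    expect_identical(local_align(q, t)$score, oracle_local_score(q, t))
  }
})

test_that("alignment score decomposes into match/mismatch/gap counts", {
  set.seed(77)
  for (i in 1:50) {
    q <- rand_seq(sample(10:60, 1))
    t <- rand_seq(sample(10:60, 1))
    a <- local_align(q, t)
    expect_equal(a$score, a$n_match - a$n_mismatch - (a$n_gap + a$n_gap_cols))
  }
})

test_that("local alignment score is symmetric and suffix-monotone", {
  set.seed(42)
  for (i in 1:50) {
    q <- rand_seq(sample(5:40, 1))
    t <- rand_seq(sample(5:40, 1))
    expect_identical(local_align(q, t)$score, local_align(t, q)$score)
    sfx <- rand_seq(8)
    expect_gte(local_align(paste0(q, sfx), paste0(t, sfx))$score,
               local_align(q, t)$score)
  }
})

test_that("heuristic mapper agrees with full DP on divergent long pairs", {
  set.seed(9)
  for (i in 1:8) {
    t <- rand_seq(1500)
    q <- mutate_sequence(t, error_model(0.07, 0.04, 0.04), seed = i)
    h <- local_align(q, t, method = "heuristic")
    f <- local_align(q, t, method = "full")
    expect_identical(h$score, f$score)
  }
})

test_that("segment identity is edit-distance based with max-length denominator", {
  expect_equal(segment_identity("ACGT", "ACGT"), 1.0)
  expect_equal(segment_identity("ACGT", "ACGA"), 0.75)
  # one deletion over max length 4
  expect_equal(segment_identity("ACGT", "ACG"), 0.75)
  expect_equal(segment_identity("ACGT", "ACG", mode = "ratio"), 6 / 7)
  expect_error(segment_identity("", "ACGT"), "non-empty")

  set.seed(5)
  for (i in 1:100) {
    a <- rand_seq(sample(1:60, 1))
    b <- rand_seq(sample(1:60, 1))
    # utils::adist is the independent Levenshtein oracle
    expect_equal(segment_identity(a, b),
                 1 - drop(adist(a, b)) / max(nchar(a), nchar(b)))
    expect_equal(segment_identity(a, b), segment_identity(b, a))
    expect_equal(segment_identity(a, b),
                 segment_identity(revcomp(a), revcomp(b)))
    expect_equal(segment_identity(a, a), 1.0)
    if (a != b) expect_lt(segment_identity(a, b), 1.0)
  }
})

test_that("banded edit distance equals the full computation at these error rates", {
  set.seed(31)
  for (i in 1:10) {
    a <- rand_seq(3000)
    b <- mutate_sequence(a, error_model(0.15, 0.08, 0.08), seed = i)
    expect_identical(rrnprofile:::cpp_banded_edit_distance(a, b, 151L),
                     rrnprofile:::cpp_edit_distance(a, b))
  }
})

test_that("nearest-rank percentile thresholds match their definition", {
  expect_equal(percentile_threshold(1:100, 50)$threshold, 50)
  expect_equal(percentile_threshold(c(10, 20, 30, 40), 25)$threshold, 10)

  set.seed(3)
  v <- runif(37)
  for (pct in c(0, 10, 25, 50, 90, 100)) {
    pt <- percentile_threshold(v, pct)
    expect_equal(pt$threshold, sort(v)[max(1, ceiling(length(v) * pct / 100))])
    expect_equal(pt$n_above, sum(v > pt$threshold))
  }
  expect_equal(percentile_threshold(v, 0)$threshold, min(v))
  expect_error(percentile_threshold(numeric(0), 50), "empty")
})

test_that("N scores as a mismatch against everything in strict mode", {
  expect_equal(local_align("NNNN", "NNNN")$score, 0)
  expect_equal(segment_identity("AN", "AN"), 0.5)
  # degenerate codes match compatible bases only in IUPAC mode (demux)
  expect_equal(local_align("ACMT", "ACAT", iupac = TRUE)$score, 4)
  expect_equal(local_align("ACMT", "ACAT", iupac = FALSE)$score, 2)
})
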
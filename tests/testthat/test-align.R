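test_that("self and disjoint alignments are the trivial limits", {
  h <- smith_waterman("ACGTACGTAC", "ACGTACGTAC")
  expect_equal(h$score, 10)
  expect_equal(h$identity, 1.0)
  expect_equal(h$query_span, c(1, 10))
  expect_equal(smith_waterman("AAAA", "CCCC")$score, 0)
  expect_error(smith_waterman("", "ACGT"), "empty")
})

test_that("local score equals brute force over all substring pairs", {
  set.seed(21)
  for (i in 1:60) {
    a <- rand_seq(8)
    b <- rand_seq(8)
    expect_equal(smith_waterman(a, b)$score, oracle_local_score(a, b),
                 info = paste(a, b))
  }
})

test_that("score is symmetric and reverse-complement invariant", {
  set.seed(22)
  for (i in 1:25) {
    a <- rand_seq(sample(10:40, 1))
    b <- rand_seq(sample(10:40, 1))
    s <- smith_waterman(a, b)$score
    expect_equal(smith_waterman(b, a)$score, s)
    expect_equal(smith_waterman(revcomp(a), revcomp(b))$score, s)
  }
})

test_that("evalue follows the Karlin-Altschul closed form", {
  expect_equal(evalue(20, 100, 100, K = 0.1, lambda = 1.0),
               0.1 * 1e4 * exp(-20))
  # linear in each length
  expect_equal(evalue(15, 200, 50), 2 * evalue(15, 100, 50))
  # monotone decreasing in score
  expect_lt(evalue(30, 100, 100), evalue(20, 100, 100))
  expect_lt(evalue(1000, 100, 100), 1e-300 + 1e-300)
  expect_error(evalue(10, 100, 100, K = 0), "positive")
  expect_error(evalue(10, 0, 100), "lengths")
})

test_that("percent similarity counts substitutions exactly", {
  set.seed(23)
  a <- rand_seq(100)
  expect_equal(percent_similarity(a, a), 1.0)
  v <- strsplit(a, "")[[1]]
  pos <- sample(100, 10)
  v[pos] <- vapply(v[pos], function(b) setdiff(c("A", "C", "G", "T"), b)[1],
                   "")
  expect_equal(percent_similarity(a, paste(v, collapse = "")), 0.90)
})
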
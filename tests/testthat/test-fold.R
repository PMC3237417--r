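test_that("forced folds behave as dictated by complementarity", {
  f <- fold("GGGAAACCC")
  expect_equal(f$n_pairs, 3L)
  expect_equal(dot_bracket(f), "(((...)))")
  sf <- structural_features(f, 0, 3)
  expect_equal(sf$stem_length, 3L)
  expect_equal(sf$loop_length, 3L)
  expect_equal(sf$match_ratio, 6 / 9)
  expect_equal(sf$mir_loop_distance, 0L)  # mature abuts the loop

  expect_equal(fold(strrep("A", 30))$n_pairs, 0L)
  expect_equal(structural_features(fold(strrep("A", 30)))$match_ratio, 0)
  expect_error(fold("ACG"), "too short")
  expect_error(fold("ACGTX"), "ACGUTN")
})

test_that("fold pair count equals exhaustive enumeration (<= 14 nt)", {
  set.seed(42)
  for (i in 1:80) {
    s <- rand_seq(sample(5:14, 1))
    expect_equal(fold(s)$n_pairs, oracle_max_pairs(s), info = s)
  }
})

test_that("appending the reverse complement never decreases pair count", {
  set.seed(7)
  for (i in 1:20) {
    s <- rand_seq(sample(10:40, 1))
    expect_gte(fold(paste0(s, revcomp(s)))$n_pairs, fold(s)$n_pairs)
  }
})

# perfect hairpin with selective N-knockouts: N never pairs, so knocking
# out a mature position and its partner creates a deterministic mismatch
knockout_hairpin <- function(arm, loop, positions = integer(0)) {
  n <- nchar(arm)
  v <- strsplit(paste0(arm, loop, revcomp(arm)), "")[[1]]
  for (p in positions) {
    v[p] <- "N"
    v[2 * n + nchar(loop) + 1 - p] <- "N"   # partner on the 3' arm
  }
  paste(v, collapse = "")
}

test_that("mircheck applies the mismatch criteria at their boundaries", {
  set.seed(11)
  arm <- rand_seq(40)
  loop <- "AACAA"
  mature_off <- 5L
  mature_len <- 21L
  pre <- knockout_hairpin(arm, loop)
  v <- mircheck(fold(pre), mature_off, mature_len)
  expect_true(v$pass)
  expect_equal(v$mismatches_mir, 0L)
  expect_equal(v$arm, "5p")

  # 4 isolated knocked-out mature positions: at the <=4 boundary, passes
  v4 <- mircheck(fold(knockout_hairpin(arm, loop, c(8, 11, 14, 17))),
                 mature_off, mature_len)
  expect_true(v4$pass)
  expect_equal(v4$mismatches_mir, 4L)

  # 5 unpaired mature positions: fails the <=4 criterion
  v5 <- mircheck(fold(knockout_hairpin(arm, loop, c(8, 11, 14, 17, 20))),
                 mature_off, mature_len)
  expect_false(v5$pass)
  expect_gte(v5$mismatches_mir, 5L)

  # 3 consecutive unpaired mature positions: fails the <=2 run criterion
  v3 <- mircheck(fold(knockout_hairpin(arm, loop, c(12, 13, 14))),
                 mature_off, mature_len)
  expect_false(v3$pass)
  expect_gte(v3$max_consecutive_mismatches, 3L)

  # mature spanning the loop fails with a reason, not an error
  vl <- mircheck(fold(pre), 35L, 21L)
  expect_false(vl$pass)
  expect_match(vl$reason, "loop")
})

test_that("mature on the 3' arm is measured symmetrically", {
  set.seed(13)
  arm <- rand_seq(40)
  pre <- paste0(arm, "AACAA", revcomp(arm))
  off3 <- 40L + 5L + 10L
  v <- mircheck(fold(pre), off3, 21L)
  expect_true(v$pass)
  expect_equal(v$arm, "3p")
  sf <- structural_features(fold(pre), off3, 21L)
  expect_equal(sf$mir_loop_distance, 10L)
})
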
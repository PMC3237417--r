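test_that("target scoring follows the complementarity rules", {
  set.seed(61)
  mature <- rand_seq(21)
  site <- revcomp(mature)
  hits <- predict_targets(mature, c(g1 = paste0("AAAA", site, "GGGG")))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$score, 0)
  expect_equal(hits$site_start, 5L)
  expect_equal(hits$cleave_pairs, 2L)
  expect_equal(hits$pairing, strrep("|", 21))

  # one G:U wobble at mature position 15 scores 0.5 (outside the 2-13
  # doubled region)
  mv <- strsplit(mature, "")[[1]]
  mv[15] <- "G"
  m2 <- paste(mv, collapse = "")
  sv <- strsplit(revcomp(m2), "")[[1]]
  sv[21 - 15 + 1] <- "T"
  h2 <- predict_targets(m2, c(g1 = paste(sv, collapse = "")))
  expect_equal(h2$score, 0.5)
  # the same wobble inside the seed-proximal region counts double
  mv[10] <- "G"
  m3 <- paste(mv, collapse = "")
  sv3 <- strsplit(revcomp(m3), "")[[1]]
  sv3[21 - 15 + 1] <- "T"
  sv3[21 - 10 + 1] <- "T"
  h3 <- predict_targets(m3, c(g1 = paste(sv3, collapse = "")))
  expect_equal(h3$score, 1.5)
  expect_equal(h3$cleave_pairs, 1L)

  # sites above the cutoff are not reported
  expect_equal(nrow(predict_targets(mature, c(gx = rand_seq(25)),
                                    max_score = 0)), 0L)
})

test_that("siRNA counting discards mature-overlapping loci", {
  m <- data.frame(chrom = "chr1", start = 100L, end = 300L,
                  mature_start = 150L, mature_end = 171L)
  tr <- data.frame(chrom = "chr1",
                   start = c(110L, 140L, 200L, 171L, 1000L),
                   end = c(134L, 164L, 224L, 195L, 1024L),
                   name = "si", score = 0L, strand = "+")
  # 4 in precursor; one overlaps the mature; one abuts it (half-open, kept)
  expect_equal(count_sirnas(m, tr), 3L)
  expect_equal(count_sirnas(m, NULL), 0L)
})

test_that("SSR detection finds planted repeats and little else", {
  set.seed(62)
  flank <- rand_seq(400)
  genome <- c(chr1 = paste0(flank, strrep("AT", 10), rand_seq(400),
                            strrep("C", 250)))
  iv <- data.frame(chrom = "chr1", start = 420L + 400L, end = 420L + 650L)
  # left flank holds the (AT)x10 plant
  expect_gte(find_ssrs(genome, iv, flank = 500L), 1L)
  # random 1 kb flanks are almost always SSR-free at these thresholds
  set.seed(63)
  counts <- vapply(1:40, function(i) {
    g <- c(chr1 = rand_seq(2300))
    find_ssrs(g, data.frame(chrom = "chr1", start = 1000L, end = 1300L))
  }, 0L)
  expect_lt(mean(counts), 0.2)
  # chromosome-edge windows truncate without error
  g <- c(chr1 = rand_seq(300))
  expect_equal(find_ssrs(g, data.frame(chrom = "chr1", start = 0L,
                                       end = 300L)), 0L)
})

test_that("track density is sites over interval length", {
  iv <- data.frame(chrom = "chr1", start = 0L, end = 100L)
  tr <- data.frame(chrom = "chr1", start = c(0L, 10L, 20L, 30L, 40L, 500L),
                   end = c(1L, 11L, 21L, 31L, 41L, 501L),
                   name = "mC", score = 0L, strand = "+")
  expect_equal(track_density(iv, tr), 0.05)
  expect_equal(track_density(iv, NULL), 0)
  expect_equal(track_density(iv, tr[tr$start > 400, ]), 0)
})

test_that("group comparison is calibrated under the null and powered", {
  set.seed(64)
  ps <- vapply(1:200, function(i) {
    compare_groups(stats::rnorm(40), rep(c(TRUE, FALSE), each = 20),
                   "numeric")$p
  }, 0)
  ks <- stats::ks.test(ps, "punif")
  expect_gt(ks$p.value, 0.001)
  # +20 nt precursor-length shift at n = 30/group (sd 15): p < 0.01 in
  # at least 90% of replicates
  hits <- vapply(1:200, function(i) {
    v <- c(stats::rnorm(30, 190, 15), stats::rnorm(30, 170, 15))
    compare_groups(v, rep(c(TRUE, FALSE), each = 30), "numeric")$p < 0.01
  }, TRUE)
  expect_gte(mean(hits), 0.9)
  # degenerate empty group yields NA, not an error
  expect_true(is.na(compare_groups(1:5, rep(TRUE, 5), "numeric")$p))
})

test_that("the feature panel separates planted de novo from conserved", {
  b <- small_bundle()
  res <- classify_bundle(b)
  feats <- compute_features(b, res)
  expect_equal(nrow(feats), nrow(b$mirnas))
  expect_true(all(feats$match_ratio >= 0 & feats$match_ratio <= 1))
  # conserved plants recur in the 3 synthetic species catalogs
  truth <- b$truth[match(feats$mirna_id, b$truth$mirna_id), ]
  cons <- truth$true_origin %in% c("TD", "SD")
  expect_true(all(feats$conservation[cons] >= 1))
  expect_true(all(feats$conservation[!cons] == 0))
  tabs <- build_tables(b, res, feats)
  expect_setequal(tabs$groups$de_novo,
                  b$truth$mirna_id[b$truth$true_origin %in% c("TR", "PR")])
  expect_true(all(c("copy_number", "splice_number", "pct_segmental",
                    "pct_tandem") %in% tabs$table2$feature))
  # methylation was planted denser in de novo precursors
  r <- tabs$table1[tabs$table1$feature == "methylcytosine_density", ]
  expect_gt(r$de_novo, r$conserved)
})
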
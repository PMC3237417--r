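# helper: hand-built hairpin miRNA row (mature on the 3' arm)
toy_mirna <- function(arm, loop = "AACAAC", chrom = "chr1", start = 0L,
                      id = "mir1", family = "fam1") {
  pre <- paste0(arm, loop, revcomp(arm))
  off <- nchar(arm) + nchar(loop) + 10L
  data.frame(id = id, chrom = chrom, start = start,
             end = start + nchar(pre), strand = "+", family = family,
             mature_start = start + off, mature_end = start + off + 21L,
             n_mature = 1L, precursor_seq = pre, mature_offset = off,
             mature_len = 21L,
             mature_seq = substring(pre, off + 1, off + 21),
             stringsAsFactors = FALSE)
}

toy_gene <- function(id, cdna, start = 0L) {
  data.frame(id = id, chrom = "chr1", start = start,
             end = start + nchar(cdna), strand = "+", isoform_count = 1L,
             rank = 1, cdna_seq = cdna, protein_seq = NA_character_,
             stringsAsFactors = FALSE)
}

test_that("TE coverage rule applies the 50% boundary", {
  m <- data.frame(chrom = "chr1", start = 0L, end = 100L)
  rep_at <- function(s, e) {
    data.frame(chrom = "chr1", start = s, end = e, strand = "+",
               family = "f", repeat_class = "LTR/Gypsy", divergence = 5,
               score = 1L, is_mite = FALSE)
  }
  expect_true(classify_te_related(m, rep_at(0, 50))$flag)
  expect_false(classify_te_related(m, rep_at(0, 49))$flag)
  r <- classify_te_related(m, rep_at(-10, 500))
  expect_true(r$flag)
  expect_equal(r$covered_bp, 100L)
  # union across fragmented features, not the best single one
  frag <- rbind(rep_at(0, 30), rep_at(10, 40), rep_at(40, 60))
  expect_true(classify_te_related(m, frag)$flag)
  # any-overlap reading is selectable
  cfg <- classify_config(any_overlap = TRUE)
  expect_true(classify_te_related(m, rep_at(0, 1), cfg)$flag)
})

test_that("inverted duplication needs both arms, identity and the mature", {
  set.seed(41)
  arm <- rand_seq(60)
  m <- toy_mirna(arm)
  # cDNA carrying the sense arm: both orientations of the palindromic
  # precursor align, and the mature (3' arm) falls in the reverse match
  g_exact <- toy_gene("g1", paste0(rand_seq(100), arm, rand_seq(100)))
  hits <- detect_inverted_duplication(m, g_exact)
  expect_equal(hits$gene_id, "g1")
  # the planted arm is exact; chance extension may dilute identity a bit
  expect_gt(hits$identity_fwd, 0.8)
  expect_gt(hits$identity_rev, 0.8)

  # identity degraded to ~0.75 fails the > 0.8 threshold
  v <- strsplit(arm, "")[[1]]
  pos <- seq(1, 60, by = 4)
  v[pos] <- vapply(v[pos], function(b) setdiff(c("A", "C", "G", "T"), b)[1],
                   "")
  g_far <- toy_gene("g2", paste0(rand_seq(100), paste(v, collapse = ""),
                                 rand_seq(100)))
  expect_equal(nrow(detect_inverted_duplication(m, g_far)), 0L)

  # matched region that excludes the mature span yields no call
  g_part <- toy_gene("g3", paste0(rand_seq(100), substring(arm, 1, 25),
                                  rand_seq(100)))
  expect_equal(nrow(detect_inverted_duplication(m, g_part)), 0L)
})

test_that("tandem duplication applies the <15000 bp and E-value clauses", {
  set.seed(42)
  arm <- rand_seq(60)
  a <- toy_mirna(arm, id = "a", family = "famX", start = 0L)
  pre_len <- a$end - a$start
  at_gap <- function(gap, id, family, arm2 = arm) {
    toy_mirna(arm2, id = id, family = family, start = a$end + gap)
  }
  b1 <- at_gap(14999L, "b1", "famX")
  expect_equal(nrow(detect_tandem_duplication(rbind(a, b1))), 1L)
  b2 <- at_gap(15000L, "b2", "famX")
  expect_equal(nrow(detect_tandem_duplication(rbind(a, b2))), 0L)
  # unrelated family but near-identical precursor: E-value clause
  b3 <- at_gap(1000L, "b3", "famY")
  td <- detect_tandem_duplication(rbind(a, b3))
  expect_equal(nrow(td), 1L)
  expect_false(td$same_family)
  expect_lt(td$evalue, 1e-10)
  # unrelated family and unrelated sequence: no call
  b4 <- at_gap(1000L, "b4", "famZ", arm2 = rand_seq(60))
  expect_equal(nrow(detect_tandem_duplication(rbind(a, b4))), 0L)
})

test_that("planted origins and mechanisms are recovered end to end", {
  b <- small_bundle()
  res <- classify_bundle(b)
  rec <- evaluate_recovery(res$calls, b$truth)
  expect_gte(rec$origin_recovery, 0.9)
  expect_gte(rec$mechanism_recovery, 0.8)
  # mechanism plants carry the matching labels
  merged <- merge(res$calls, b$truth, by = "mirna_id")
  for (mech in c("A", "B")) {
    rows <- merged[merged$true_mechanism == mech, ]
    expect_true(all(grepl("TR", rows$labels)), info = mech)
  }
  for (mech in c("C", "D")) {
    rows <- merged[merged$true_mechanism == mech, ]
    expect_true(all(grepl("PR", rows$labels)), info = mech)
  }
  # multi-label: no forced exclusivity, OT iff nothing else
  ot <- grepl("OT", res$calls$labels)
  expect_true(all(res$calls$labels[ot] == "OT"))
  expect_equal(sum(res$counts$n_primary), nrow(res$calls))
})

test_that("an all-background genome classifies everything as OT", {
  cfg <- synth_config(genome_length = 30000, n_nonmite_id = 0,
                      n_mite_id = 0, n_pseudo_same = 0,
                      n_pseudo_paralog = 0, n_tandem = 0, n_segmental = 0,
                      n_background = 4, n_coding_genes = 4,
                      te_fraction = 0, seed = 44)
  b <- generate_genome(cfg, withr::local_tempdir())
  res <- classify_bundle(b)
  expect_equal(nrow(res$calls), 4L)
  expect_true(all(res$calls$labels == "OT"))
  expect_true(all(res$calls$mechanism == "none"))
})
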
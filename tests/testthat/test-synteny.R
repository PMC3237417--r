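test_that("a perfect diagonal chains into one block", {
  anchors <- data.frame(gene_a = sprintf("a%d", 1:5),
                        gene_b = sprintf("b%d", 1:5),
                        pos_a = 1:5, pos_b = 101:105, score = 100,
                        stringsAsFactors = FALSE)
  chains <- chain_anchors(anchors)
  expect_length(chains, 1)
  expect_equal(nrow(chains[[1]]$anchors), 5L)
  # antidiagonal (inverted block) chains too
  anchors$pos_b <- 105:101
  expect_equal(nrow(chain_anchors(anchors)[[1]]$anchors), 5L)
})

test_that("optimal chain equals exhaustive search for <= 8 anchors", {
  set.seed(51)
  for (rep in 1:30) {
    a <- rand_anchors(sample(4:8, 1))
    ora <- oracle_best_chain(a)
    dp <- mirorigin:::best_chain_dp(a[order(a$pos_a, a$pos_b), ],
                                    gap_penalty = 1, max_gap_genes = 25L)
    expect_equal(dp$score, ora$score, tolerance = 1e-9, info = rep)
  }
})

test_that("shuffled anchor orders almost never chain", {
  set.seed(52)
  base <- data.frame(gene_a = sprintf("a%d", 1:5),
                     gene_b = sprintf("b%d", 1:5),
                     pos_a = 1:5, pos_b = 101:105, score = 100,
                     stringsAsFactors = FALSE)
  hits <- vapply(1:200, function(i) {
    sh <- base
    sh$pos_b <- sample(sh$pos_b)
    any(vapply(chain_anchors(sh), function(ch) nrow(ch$anchors) >= 3, TRUE))
  }, TRUE)
  expect_lte(mean(hits), 0.05)
})

test_that("family criterion formula is continuous with the 30% rule", {
  expect_equal(family_criterion_I(150), 0.30)
  expect_lt(abs(family_criterion_I(149.9999) - 0.30), 0.01)
  expect_gt(family_criterion_I(50), family_criterion_I(149))
})

test_that("protein family clustering applies both criteria", {
  set.seed(53)
  p1 <- rand_seq(200, strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  p35 <- mutate_fraction(p1, 0.65, 531)   # ~35% identity over L = 200
  p25 <- mutate_fraction(p1, 0.75, 532)   # ~25% identity
  fam <- cluster_protein_families(c(a = p1, b = p35))
  expect_equal(fam[["a"]], fam[["b"]])
  fam2 <- cluster_protein_families(c(a = p1, b = p25))
  expect_false(fam2[["a"]] == fam2[["b"]])
  # order independence
  fam_r <- cluster_protein_families(c(b = p35, a = p1))
  expect_equal(fam_r[["a"]], fam_r[["b"]])
})

test_that("tandem arrays use the fewer-than-20-intervening-genes rule", {
  mk_genes <- function(ranks) {
    data.frame(id = sprintf("g%d", seq_along(ranks)), chrom = "chr1",
               start = ranks * 1000L, end = ranks * 1000L + 500L,
               strand = "+", isoform_count = 1L, rank = ranks,
               stringsAsFactors = FALSE)
  }
  fam_pair <- c(g1 = 1L, g2 = 1L)
  # 19 genes between (rank difference 20): tandem
  g <- mk_genes(c(1L, 21L))
  expect_length(tandem_gene_arrays(fam_pair, g), 1)
  # 20 genes between (rank difference 21): not tandem
  g <- mk_genes(c(1L, 22L))
  expect_length(tandem_gene_arrays(fam_pair, g), 0)
  # transitive closure: chain of 3 paralogs, 5 apart, one array of 3
  fam3 <- c(g1 = 1L, g2 = 1L, g3 = 1L)
  g <- mk_genes(c(1L, 7L, 13L))
  arr <- tandem_gene_arrays(fam3, g)
  expect_length(arr, 1)
  expect_setequal(arr[[1]], c("g1", "g2", "g3"))
})

test_that("segmental miRNA pairs require both the block and relatedness", {
  b <- small_bundle()
  res <- classify_bundle(b)
  truth_sd <- sort(b$truth$mirna_id[b$truth$true_origin == "SD"])
  called_sd <- sort(unique(c(res$sd_pairs$id_a, res$sd_pairs$id_b)))
  expect_equal(called_sd, truth_sd)
  # with no chains there is no call
  none <- segmental_mirna_pairs(b$mirnas, list(), b$genes)
  expect_equal(nrow(none), 0L)
})
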
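test_that("inverted repeat pairs obey the zero-mutation limit", {
  set.seed(31)
  src <- rand_seq(80)
  p <- plant_inverted_repeat_pair(src, spacer_len = 3, mutation_rate = 0)
  expect_equal(p$arm_similarity, 1.0)
  expect_equal(p$locus, paste0(src, p$spacer, revcomp(src)))
  # spacer of 3 folds into a 3-nt hairpin loop
  f <- fold(p$locus)
  l <- mirorigin:::hairpin_loops(f)[[1]]
  expect_equal(unname(l["end"] - l["start"] + 1L), 3L)
  expect_error(plant_inverted_repeat_pair(rand_seq(50)), "too short")
  expect_error(plant_inverted_repeat_pair(src, spacer_len = 2), "spacer")
})

test_that("arm similarity matches the binomial expectation", {
  set.seed(32)
  src <- rand_seq(100)
  sim_at <- function(rate, n) {
    mean(vapply(seq_len(n), function(i) {
      plant_inverted_repeat_pair(src, 6, rate)$arm_similarity
    }, 0))
  }
  # two independently mutated copies match when neither site mutated or
  # both hit the same base: (1-r)^2 + r^2/3
  r <- 0.02
  expect_equal(sim_at(r, 100), (1 - r)^2 + r^2 / 3, tolerance = 0.01)
  # at rate 0.5 similarity collapses far below the 80% demand
  expect_lt(sim_at(0.5, 50), 0.5)
})

test_that("generation is deterministic and internally consistent", {
  cfg <- synth_config(genome_length = 60000, n_nonmite_id = 1,
                      n_mite_id = 1, n_pseudo_same = 1,
                      n_pseudo_paralog = 1, n_tandem = 2, n_segmental = 2,
                      n_background = 1, n_coding_genes = 5, seed = 33)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  b <- generate_genome(cfg, d1)
  generate_genome(cfg, d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  expect_identical(unname(tools::md5sum(file.path(d1, f1))),
                   unname(tools::md5sum(file.path(d2, f1))))

  # truth covers every emitted miRNA
  expect_setequal(b$truth$mirna_id, b$mirnas$id)
  # precursor sequences equal the genome slice (verified by read-back)
  expect_true(all(nchar(b$mirnas$precursor_seq) ==
                    b$mirnas$end - b$mirnas$start))
  # every planted foldback passes the MIRcheck filter at emission
  for (i in seq_len(nrow(b$mirnas))) {
    v <- mircheck(fold(b$mirnas$precursor_seq[i]),
                  b$mirnas$mature_offset[i], b$mirnas$mature_len[i])
    expect_true(v$pass, info = b$mirnas$id[i])
  }
})

test_that("degenerate all-zero config yields an empty annotated genome", {
  cfg <- synth_config(genome_length = 4000, n_nonmite_id = 0, n_mite_id = 0,
                      n_pseudo_same = 0, n_pseudo_paralog = 0, n_tandem = 0,
                      n_segmental = 0, n_background = 0, n_coding_genes = 0,
                      te_fraction = 0, seed = 34)
  b <- generate_genome(cfg, withr::local_tempdir())
  expect_equal(nrow(b$mirnas), 0L)
  expect_equal(nrow(b$truth), 0L)
  expect_equal(nrow(b$repeats), 0L)
  expect_equal(nchar(b$genome[["chr1"]]), 4000L)
})

test_that("retry exhaustion names the failing mechanism", {
  cfg <- synth_config(genome_length = 60000, n_nonmite_id = 1,
                      n_mite_id = 0, n_pseudo_same = 0,
                      n_pseudo_paralog = 0, n_tandem = 0, n_segmental = 0,
                      n_background = 0, n_coding_genes = 0,
                      mutation_rate = 0.5, max_retries = 5, seed = 35)
  expect_error(generate_genome(cfg, withr::local_tempdir()),
               "mechanism A")
})

test_that("config validation rejects out-of-range values", {
  expect_error(synth_config(te_fraction = 1.5), "fractions")
  expect_error(synth_config(mutation_rate = -0.1), "mutation_rate")
  expect_error(synth_config(n_tandem = -1), "counts")
  # planted content must fit the declared genome length
  cfg <- synth_config(genome_length = 2000, seed = 36)
  expect_error(generate_genome(cfg, withr::local_tempdir()), "too small")
})
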
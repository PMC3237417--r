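# Independent oracles used across the suite. These deliberately use
# different algorithms (explicit enumeration) from the package's dynamic
# programs.

# exhaustive maximum pairing over all nested structures (min loop 3):
# recursion over "position 1 unpaired or paired with k", counting pairs,
# without the Nussinov interval table
oracle_max_pairs <- function(seq, min_loop = 3L) {
  v <- strsplit(chartr("T", "U", toupper(seq)), "")[[1]]
  ok <- function(a, b) {
    paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  }
  rec <- function(i, j) {
    if (j - i < min_loop + 1L) return(0L)
    best <- rec(i + 1L, j)
    for (k in (i + min_loop + 1L):j) {
      if (!ok(v[i], v[k])) next
      best <- max(best, 1L + rec(i + 1L, k - 1L) +
                    (if (k < j) rec(k + 1L, j) else 0L))
    }
    best
  }
  rec(1L, length(v))
}

# brute-force local alignment: best affine-gap *global* score over all
# substring pairs, computed by a plain 3-state recursion per pair
oracle_local_score <- function(a, b, match = 1, mismatch = -1,
                               gap_open = -2, gap_extend = -1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  global_affine <- function(x, y) {
    n <- length(x); m <- length(y)
    NEG <- -1e9
    M <- matrix(NEG, n + 1, m + 1)   # last op diagonal
    E <- matrix(NEG, n + 1, m + 1)   # last op gap in y
    F <- matrix(NEG, n + 1, m + 1)   # last op gap in x
    M[1, 1] <- 0
    for (i in seq_len(n)) {
      E[i + 1, 1] <- max(M[i, 1] + gap_open, E[i, 1] + gap_extend)
    }
    for (j in seq_len(m)) {
      F[1, j + 1] <- max(M[1, j] + gap_open, F[1, j] + gap_extend)
    }
    for (i in seq_len(n)) {
      for (j in seq_len(m)) {
        s <- if (x[i] == y[j]) match else mismatch
        M[i + 1, j + 1] <- max(M[i, j], E[i, j], F[i, j]) + s
        E[i + 1, j + 1] <- max(M[i, j + 1] + gap_open,
                               E[i, j + 1] + gap_extend)
        F[i + 1, j + 1] <- max(M[i + 1, j] + gap_open,
                               F[i + 1, j] + gap_extend)
      }
    }
    max(M[n + 1, m + 1], E[n + 1, m + 1], F[n + 1, m + 1])
  }
  best <- 0
  for (i1 in seq_along(av)) for (j1 in i1:length(av)) {
    for (i2 in seq_along(bv)) for (j2 in i2:length(bv)) {
      best <- max(best, global_affine(av[i1:j1], bv[i2:j2]))
    }
  }
  best
}

# exhaustive best collinear chain over <= 8 anchors: enumerate all subsets
# (ordered by pos_a), keep those strictly increasing in pos_a, strictly
# monotonic in pos_b, within the gap bound, score as the chainer does
oracle_best_chain <- function(anchors, gap_penalty = 1,
                              max_gap_genes = 25L) {
  n <- nrow(anchors)
  a <- anchors[order(anchors$pos_a, anchors$pos_b), , drop = FALSE]
  best <- list(score = -Inf, members = integer(0))
  for (mask in seq_len(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    pa <- a$pos_a[idx]; pb <- a$pos_b[idx]
    if (any(diff(pa) <= 0)) next
    if (length(idx) >= 2) {
      db <- diff(pb)
      if (!(all(db > 0) || all(db < 0))) next
      if (any(diff(pa) - 1 > max_gap_genes)) next
      if (any(abs(db) - 1 > max_gap_genes)) next
    }
    w <- sum(log(1 + a$score[idx]))
    if (length(idx) >= 2) {
      w <- w - gap_penalty * sum((diff(pa) - 1) + (abs(diff(pb)) - 1))
    }
    if (w > best$score) best <- list(score = w, members = idx)
  }
  best
}

rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

rand_anchors <- function(n) {
  data.frame(gene_a = sprintf("a%d", seq_len(n)),
             gene_b = sprintf("b%d", seq_len(n)),
             pos_a = sort(sample(1:40, n)), pos_b = sample(1:40, n),
             score = round(stats::runif(n, 50, 500)),
             stringsAsFactors = FALSE)
}

# protein with an exact fraction of substituted positions
mutate_fraction <- function(p, frac, seed) {
  set.seed(seed)
  v <- strsplit(p, "")[[1]]
  pos <- sample(length(v), round(frac * length(v)))
  alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  v[pos] <- vapply(v[pos], function(b) setdiff(alphabet, b)[1], "")
  paste(v, collapse = "")
}

# small bundle shared by several test files (cached per session)
small_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "mirorigin-small-bundle")
      cfg <- synth_config(genome_length = 120000, n_nonmite_id = 2,
                          n_mite_id = 2, n_pseudo_same = 2,
                          n_pseudo_paralog = 2, n_tandem = 4,
                          n_segmental = 4, n_background = 2,
                          n_coding_genes = 12, seed = 101)
      cache <<- generate_genome(cfg, dir)
    }
    cache
  }
})
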
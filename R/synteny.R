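# Segmental duplication blocks by collinear anchor chaining, tandem gene
# arrays, and protein family clustering with the alignable-length-dependent
# similarity criterion.

#' Protein anchor pairs for synteny chaining
#'
#' All-versus-all local protein alignment; pairs with E below
#' `anchor_evalue` qualify as anchors. Self pairs and tandem-range pairs
#' (rank difference below `tandem_range` on one chromosome) are excluded
#' before chaining, as is standard for self-comparisons.
#'
#' @param genes gene data.frame with protein_seq and rank
#' @param tandem_range rank-difference exclusion window (default 20)
#' @param cfg a [classify_config()]
#' @return data.frame: gene_a, gene_b, pos_a, pos_b, score
#' @export
protein_anchors <- function(genes, tandem_range = 20L,
                            cfg = classify_config()) {
  out <- list()
  n <- nrow(genes)
  if (n >= 2 && !is.null(genes$protein_seq)) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (genes$chrom[i] == genes$chrom[j] &&
            abs(genes$rank[i] - genes$rank[j]) < tandem_range) next
        hit <- smith_waterman(genes$protein_seq[i], genes$protein_seq[j],
                              K = cfg$K, lambda = cfg$lambda,
                              wildcard = "X")
        if (hit$evalue >= cfg$anchor_evalue) next
        out[[length(out) + 1L]] <- data.frame(
          gene_a = genes$id[i], gene_b = genes$id[j],
          pos_a = genes$rank[i], pos_b = genes$rank[j], score = hit$score,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else data.frame(
    gene_a = character(0), gene_b = character(0), pos_a = numeric(0),
    pos_b = numeric(0), score = numeric(0), stringsAsFactors = FALSE)
}

# chain score: sum of log(1 + anchor score) minus gap_penalty per skipped
# gene rank on either genome copy
chain_score <- function(anchors, idx, gap_penalty) {
  w <- log(1 + anchors$score[idx])
  s <- sum(w)
  if (length(idx) >= 2) {
    da <- diff(anchors$pos_a[idx])
    db <- abs(diff(anchors$pos_b[idx]))
    s <- s - gap_penalty * sum((da - 1) + (db - 1))
  }
  s
}

#' Chain anchors into collinear segmental-duplication blocks
#'
#' Sparse dynamic programming over anchors ordered by pos_a: chains are
#' strictly increasing in pos_a, monotonic (increasing or decreasing) in
#' pos_b, with at most `max_gap_genes` skipped ranks per step. Maximal
#' chains are extracted greedily (best chain first, anchors used once);
#' chains shorter than `min_anchors` are dropped. Deterministic given the
#' input order (ties by smallest starting rank).
#'
#' @param anchors anchor data.frame from [protein_anchors()]
#' @param gap_penalty penalty per skipped gene rank
#' @param min_anchors minimum anchors per reported chain
#' @param max_gap_genes maximum skipped ranks between consecutive anchors
#' @param min_score minimum chain score (DAGchainer-style significance
#'   floor; the default rejects the short monotone runs that any shuffled
#'   anchor set contains, while keeping blocks of >= 4 strong anchors)
#' @return list of chains; each chain is a list(anchors = data.frame,
#'   score)
#' @export
chain_anchors <- function(anchors, gap_penalty = 1, min_anchors = 3L,
                          max_gap_genes = 25L, min_score = 20) {
  chains <- list()
  if (is.null(anchors) || nrow(anchors) == 0) return(chains)
  anchors <- unique(anchors)
  anchors <- anchors[anchors$gene_a != anchors$gene_b, , drop = FALSE]
  anchors <- anchors[order(anchors$pos_a, anchors$pos_b), , drop = FALSE]
  rownames(anchors) <- NULL
  avail <- rep(TRUE, nrow(anchors))
  repeat {
    idx <- which(avail)
    if (length(idx) < min_anchors) break
    aa <- anchors[idx, , drop = FALSE]
    best <- best_chain_dp(aa, gap_penalty, max_gap_genes)
    if (length(best$members) < min_anchors || best$score < min_score) break
    chains[[length(chains) + 1L]] <- list(
      anchors = aa[best$members, , drop = FALSE], score = best$score)
    avail[idx[best$members]] <- FALSE
  }
  chains
}

# best single chain by DP with direction state (pos_b up or down)
best_chain_dp <- function(a, gap_penalty, max_gap_genes) {
  n <- nrow(a)
  w <- log(1 + a$score)
  dp_up <- w; dp_dn <- w
  par_up <- rep(0L, n); par_dn <- rep(0L, n)
  for (k in seq_len(n)) {
    for (l in seq_len(k - 1L)) {
      if (a$pos_a[l] >= a$pos_a[k]) next
      da <- a$pos_a[k] - a$pos_a[l] - 1
      if (da > max_gap_genes) next
      db <- a$pos_b[k] - a$pos_b[l]
      if (db == 0) next
      gap <- da + abs(db) - 1
      if (abs(db) - 1 > max_gap_genes) next
      if (db > 0) {
        # predecessor may itself be a single anchor (direction-free) or an
        # up-chain
        cand <- max(dp_up[l], w[l]) + w[k] - gap_penalty * gap
        if (cand > dp_up[k]) { dp_up[k] <- cand; par_up[k] <- l }
      } else {
        cand <- max(dp_dn[l], w[l]) + w[k] - gap_penalty * gap
        if (cand > dp_dn[k]) { dp_dn[k] <- cand; par_dn[k] <- l }
      }
    }
  }
  if (max(dp_up) >= max(dp_dn)) {
    dp <- dp_up; par <- par_up
  } else {
    dp <- dp_dn; par <- par_dn
  }
  k <- which.max(dp)
  members <- k
  while (par[k] != 0L) {
    k <- par[k]
    members <- c(k, members)
  }
  list(members = members, score = max(dp))
}

# chain spans (bp) on both genome copies, from the anchors' gene intervals
chain_spans <- function(chain, genes) {
  ga <- genes[match(chain$anchors$gene_a, genes$id), , drop = FALSE]
  gb <- genes[match(chain$anchors$gene_b, genes$id), , drop = FALSE]
  list(a = data.frame(chrom = ga$chrom[1], start = min(ga$start),
                      end = max(ga$end)),
       b = data.frame(chrom = gb$chrom[1], start = min(gb$start),
                      end = max(gb$end)))
}

#' Segmental-duplication miRNA pairs
#'
#' A miRNA pair is segmental when the two genes fall inside the paired
#' spans of one chain and the pair is related (same family, or precursor
#' alignment E-value below `td_evalue`).
#'
#' @param mirnas miRNA data.frame
#' @param chains chain list from [chain_anchors()]
#' @param genes gene data.frame (for chain spans)
#' @param cfg a [classify_config()]
#' @return data.frame: id_a, id_b, chain
#' @export
segmental_mirna_pairs <- function(mirnas, chains, genes,
                                  cfg = classify_config()) {
  out <- list()
  if (length(chains) > 0 && nrow(mirnas) >= 2) {
    within <- function(m, span) {
      m$chrom == span$chrom & m$start >= span$start & m$end <= span$end
    }
    for (ci in seq_along(chains)) {
      sp <- chain_spans(chains[[ci]], genes)
      in_a <- which(within(mirnas, sp$a))
      in_b <- which(within(mirnas, sp$b))
      for (i in in_a) {
        for (j in in_b) {
          if (i == j) next
          related <- mirnas$family[i] == mirnas$family[j]
          if (!related && !is.null(mirnas$precursor_seq)) {
            ev <- smith_waterman(mirnas$precursor_seq[i],
                                 mirnas$precursor_seq[j],
                                 K = cfg$K, lambda = cfg$lambda)$evalue
            related <- ev < cfg$td_evalue
          }
          if (!related) next
          out[[length(out) + 1L]] <- data.frame(
            id_a = mirnas$id[min(i, j)], id_b = mirnas$id[max(i, j)],
            chain = ci, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out)) unique(do.call(rbind, out)) else data.frame(
    id_a = character(0), id_b = character(0), chain = integer(0),
    stringsAsFactors = FALSE)
}

#' Similarity threshold of the protein family criterion
#'
#' I = 30 percent when the alignable length L is at least 150 aa;
#' I = 0.01 n + 4.8 L^(-0.32 (1 + exp(-L / 1000))) below that (n = 6).
#' The printed form of this formula in its source is typographically
#' broken; this reading is the one continuous with the 30 percent rule
#' (I(150) is about 0.303).
#'
#' @param L alignable region length (aa)
#' @param n alignable-segment parameter (default 6)
#' @return similarity threshold as a fraction
#' @export
family_criterion_I <- function(L, n = 6) {
  ifelse(L >= 150, 0.30,
         0.01 * n + 4.8 * L^(-0.32 * (1 + exp(-L / 1000))))
}

#' Cluster proteins into families
#'
#' Two proteins qualify as family mates when (1) their local-alignment
#' similarity (matches / aligned columns) is at least the
#' length-dependent threshold of [family_criterion_I()], and (2) the
#' alignable region is at least 80 percent of the longer protein.
#' Families are the single-linkage closure of qualifying pairs, so the
#' partition is order-independent.
#'
#' @param proteins named character vector of protein sequences
#' @param min_align_frac alignable-length fraction of the longer protein
#' @param scoring protein alignment scoring; the default mild mismatch
#'   penalty (-0.1) keeps the expected per-column score positive down to
#'   ~12 percent identity, mimicking the positive expected score of a
#'   BLOSUM-style matrix on weakly similar regions, so the similarity and
#'   alignable-length thresholds (not the aligner) decide family
#'   membership while unrelated proteins (~5 percent identity, negative
#'   drift) still yield short alignments
#' @param cfg a [classify_config()]
#' @return named integer vector: protein name -> family id; family sizes
#'   give gene copy numbers
#' @export
cluster_protein_families <- function(proteins, min_align_frac = 0.8,
                                     scoring = list(match = 1,
                                                    mismatch = -0.1,
                                                    gap_open = -2,
                                                    gap_extend = -1),
                                     cfg = classify_config()) {
  n <- length(proteins)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        hit <- smith_waterman(proteins[i], proteins[j], scoring = scoring,
                              K = cfg$K, lambda = cfg$lambda,
                              wildcard = "X")
        L <- hit$aligned_cols
        if (L < min_align_frac * max(nchar(proteins[i]),
                                     nchar(proteins[j]))) next
        if (hit$matches / L < family_criterion_I(L)) next
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  fam <- match(roots, sort(unique(roots)))
  stats::setNames(as.integer(fam), names(proteins))
}

#' Tandem gene arrays
#'
#' Two paralogous genes (same protein family) on one chromosome separated
#' by fewer than `max_between` intervening genes are tandem; arrays are the
#' transitive closure of tandem pairs.
#'
#' @param families named family vector from [cluster_protein_families()]
#' @param genes gene data.frame with rank
#' @param max_between separation bound in genes (default 20)
#' @return list of character vectors (gene ids), one per array of size >= 2
#' @export
tandem_gene_arrays <- function(families, genes, max_between = 20L) {
  ids <- genes$id
  fam <- families[ids]
  n <- length(ids)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (is.na(fam[i]) || is.na(fam[j]) || fam[i] != fam[j]) next
        if (genes$chrom[i] != genes$chrom[j]) next
        between <- abs(genes$rank[i] - genes$rank[j]) - 1
        if (between < max_between) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  arrays <- split(ids, roots)
  unname(arrays[lengths(arrays) >= 2])
}
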
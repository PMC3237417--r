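# Per-miRNA feature panel and regulatory-system features, plus the
# simplified complementarity target matcher that substitutes for an
# external target-prediction server.

#' Predict miRNA target sites by complementarity scoring
#'
#' Ungapped scan of the mature against each cDNA. Per duplex position:
#' Watson-Crick pair 0, G:U wobble 0.5, other mismatch 1; penalties are
#' doubled at mature positions 2-13 (the seed-proximal region). Windows
#' scoring at most `max_score` are reported; overlapping windows on one
#' gene are collapsed keeping the best. The scorer supports
#' substitution-type mismatches only; the gap penalty of the miRU-style
#' scheme is documented but gapped sites are not searched.
#'
#' @param mature_seq mature miRNA sequence (19-24 nt)
#' @param genes gene data.frame with cdna_seq (and, when available,
#'   genomic interval columns used to map sites to genome coordinates), or
#'   a named character vector of cDNAs
#' @param max_score score cutoff (default 4.0)
#' @return data.frame: gene_id, site_start, site_end (1-based in cDNA),
#'   score, pairing (per-position profile string, | = Watson-Crick,
#'   o = G:U, . = mismatch), cleave_pairs (Watson-Crick count at mature
#'   positions 10 and 11), site_chrom, site_gstart, site_gend
#' @export
predict_targets <- function(mature_seq, genes, max_score = 4.0) {
  if (is.character(genes)) {
    genes <- data.frame(id = names(genes), cdna_seq = unname(genes),
                        chrom = NA_character_, start = NA_integer_,
                        end = NA_integer_, strand = "+",
                        stringsAsFactors = FALSE)
  }
  L <- nchar(mature_seq)
  stopifnot(L >= 19, L <= 24)
  out <- list()
  for (i in seq_len(nrow(genes))) {
    cdna <- genes$cdna_seq[i]
    if (is.na(cdna) || nchar(cdna) < L) next
    hits <- scan_target_sites(toupper(mature_seq), toupper(cdna),
                              max_score = max_score)
    if (nrow(hits) == 0) next
    hits <- hits[order(hits$score, hits$site_start), , drop = FALSE]
    keep <- integer(0)
    taken <- integer(0)
    for (k in seq_len(nrow(hits))) {
      s <- hits$site_start[k]
      if (length(taken) && any(abs(taken - s) < L)) next
      taken <- c(taken, s)
      keep <- c(keep, k)
    }
    hits <- hits[keep, , drop = FALSE]
    for (k in seq_len(nrow(hits))) {
      s <- hits$site_start[k]
      prof <- pairing_profile(mature_seq, substring(cdna, s, s + L - 1L))
      gstart <- if (!is.na(genes$start[i]) && genes$strand[i] == "+") {
        genes$start[i] + s - 1L
      } else NA_integer_
      out[[length(out) + 1L]] <- data.frame(
        gene_id = genes$id[i], site_start = s, site_end = s + L - 1L,
        score = hits$score[k], pairing = prof$profile,
        cleave_pairs = prof$cleave_pairs,
        site_chrom = genes$chrom[i],
        site_gstart = gstart,
        site_gend = if (is.na(gstart)) NA_integer_ else gstart + L,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else data.frame(
    gene_id = character(0), site_start = integer(0), site_end = integer(0),
    score = numeric(0), pairing = character(0), cleave_pairs = integer(0),
    site_chrom = character(0), site_gstart = integer(0),
    site_gend = integer(0), stringsAsFactors = FALSE)
}

# Watson-Crick / wobble profile of a mature against a site window; mature
# position k faces window position L - k + 1
pairing_profile <- function(mature, site) {
  mv <- strsplit(chartr("U", "T", toupper(mature)), "")[[1]]
  sv <- strsplit(toupper(site), "")[[1]]
  L <- length(mv)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  prof <- vapply(seq_len(L), function(k) {
    s <- sv[L - k + 1]
    m <- mv[k]
    if (!is.na(comp[m]) && identical(unname(comp[m]), s)) "|"
    else if ((m == "G" && s == "T") || (m == "T" && s == "G")) "o"
    else "."
  }, "")
  list(profile = paste(prof, collapse = ""),
       cleave_pairs = sum(prof[c(10, 11)] == "|"))
}

#' Count siRNAs encoded by a precursor
#'
#' siRNA loci overlapping the precursor, discarding those that overlap the
#' mature miRNA.
#'
#' @param mirna one-row miRNA data.frame
#' @param sirna_track BED-style data.frame or NULL
#' @return integer count
#' @export
count_sirnas <- function(mirna, sirna_track) {
  if (is.null(sirna_track) || nrow(sirna_track) == 0) return(0L)
  pre <- data.frame(chrom = mirna$chrom, start = mirna$start,
                    end = mirna$end)
  mat <- data.frame(chrom = mirna$chrom, start = mirna$mature_start,
                    end = mirna$mature_end)
  in_pre <- overlap_bp(sirna_track, pre) > 0
  on_mat <- overlap_bp(sirna_track, mat) > 0
  sum(in_pre & !on_mat)
}

#' Count simple sequence repeats in the 1 kb flanks of an interval
#'
#' Perfect tandem repeats with motif 1-6 bp, at least 4 units and at least
#' 12 bp total, in the `flank` bp on each side (truncated at chromosome
#' ends). Overlapping matches across motif sizes are merged before
#' counting.
#'
#' @param genome named genome vector
#' @param interval one-row interval data.frame
#' @param flank flank size in bp (default 1000)
#' @return integer count
#' @export
find_ssrs <- function(genome, interval, flank = 1000L) {
  chrom_len <- nchar(genome[[interval$chrom]])
  left <- c(max(0L, interval$start - flank), interval$start)
  right <- c(interval$end, min(chrom_len, interval$end + flank))
  n <- 0L
  for (w in list(left, right)) {
    if (w[2] - w[1] < 12) next
    seq <- slice_genome(genome, interval$chrom, w[1], w[2])
    n <- n + count_ssrs_in(seq)
  }
  n
}

count_ssrs_in <- function(seq) {
  iv <- list()
  min_units <- c(12L, 6L, 4L, 4L, 4L, 4L)  # >= 4 units and >= 12 bp total
  for (k in 1:6) {
    pat <- sprintf("([ACGT]{%d})\\1{%d,}", k, min_units[k] - 1L)
    m <- gregexpr(pat, seq, perl = TRUE)[[1]]
    if (m[1] == -1) next
    len <- attr(m, "match.length")
    for (x in seq_along(m)) {
      iv[[length(iv) + 1L]] <- c(m[x], m[x] + len[x] - 1L)
    }
  }
  if (length(iv) == 0) return(0L)
  iv <- do.call(rbind, iv)
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  merged <- 1L
  cur_end <- iv[1, 2]
  for (x in seq_len(nrow(iv))[-1]) {
    if (iv[x, 1] <= cur_end + 1L) cur_end <- max(cur_end, iv[x, 2]) else {
      merged <- merged + 1L
      cur_end <- iv[x, 2]
    }
  }
  merged
}

#' Per-bp density of track sites over an interval
#'
#' Number of track features overlapping the interval divided by interval
#' length; used for methylcytosine and polymorphic site densities.
#'
#' @param interval one-row interval data.frame
#' @param track BED-style data.frame or NULL
#' @return fraction
#' @export
track_density <- function(interval, track) {
  if (is.null(track) || nrow(track) == 0) return(0)
  sum(overlap_bp(track, interval) > 0) / (interval$end - interval$start)
}

# ortholog count: number of species catalogs holding a sequence within 2
# substitutions of the mature (equal length, no indels)
mirna_conservation <- function(mature_seq, species) {
  if (is.null(species) || length(species) == 0) return(NA_integer_)
  L <- nchar(mature_seq)
  sum(vapply(species, function(cat) {
    cat <- cat[nchar(cat) == L]
    if (length(cat) == 0) return(FALSE)
    any(vapply(cat, function(s) {
      sum(strsplit(s, "")[[1]] != strsplit(mature_seq, "")[[1]]) <= 2
    }, TRUE))
  }, TRUE))
}

#' Compute the per-miRNA feature panel
#'
#' One row per miRNA gene covering sequence, structure, genomic context,
#' regulation, conservation and expression features; NA where the needed
#' track is absent.
#'
#' @param bundle annotation bundle
#' @param result classification result from [classify_bundle()] (supplies
#'   targets and protein families); optional
#' @param cfg a [classify_config()]
#' @return data.frame of features, one row per miRNA
#' @export
compute_features <- function(bundle, result = NULL,
                             cfg = classify_config()) {
  mirnas <- bundle$mirnas
  genes <- bundle$genes
  n <- nrow(mirnas)
  expr <- bundle$expression
  expr_mean <- if (!is.null(expr)) {
    stats::setNames(rowMeans(expr[, -1, drop = FALSE]), expr$id)
  } else NULL
  fam_sizes <- table(mirnas$family)
  gene_fams <- if (!is.null(result)) result$gene_families else NULL

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    m <- mirnas[i, ]
    f <- fold(m$precursor_seq)
    sf <- structural_features(f, m$mature_offset, m$mature_len)
    tg <- if (!is.null(result)) result$targets[[m$id]] else {
      predict_targets(m$mature_seq, genes, cfg$target_max_score)
    }
    iv <- m[, c("chrom", "start", "end")]
    up <- if (m$strand == "+") {
      data.frame(chrom = m$chrom, start = max(0L, m$start - 1000L),
                 end = m$start)
    } else {
      data.frame(chrom = m$chrom, start = m$end,
                 end = min(nchar(bundle$genome[[m$chrom]]), m$end + 1000L))
    }
    tgt_expr <- if (!is.null(expr_mean) && nrow(tg) > 0) {
      mean(expr_mean[unique(tg$gene_id)], na.rm = TRUE)
    } else NA_real_
    tgt_copy <- if (!is.null(gene_fams) && nrow(tg) > 0) {
      mean(table(gene_fams)[as.character(gene_fams[unique(tg$gene_id)])])
    } else NA_real_
    rows[[i]] <- data.frame(
      mirna_id = m$id,
      first_nt_is_A = substring(m$mature_seq, 1, 1) == "A",
      mirna_length = m$mature_len,
      precursor_length = sf$precursor_length,
      stem_length = sf$stem_length,
      loop_length = sf$loop_length,
      mir_loop_distance = sf$mir_loop_distance,
      match_ratio = sf$match_ratio,
      sirna_count = count_sirnas(m, bundle$tracks$sirna),
      multi_mirna = m$n_mature > 1,
      genic_location = nrow(genes) > 0 &&
        any(overlap_bp(genes, iv) > 0),
      promoter_count = if (!is.null(bundle$tracks$promoters)) {
        sum(overlap_bp(bundle$tracks$promoters, up) > 0)
      } else NA_integer_,
      ssr_count_1kb = find_ssrs(bundle$genome, iv),
      target_number = length(unique(tg$gene_id)),
      target_expression_mean = tgt_expr,
      target_copy_number_mean = tgt_copy,
      cleaving_site_pairings = if (nrow(tg) > 0) {
        mean(tg$cleave_pairs)
      } else NA_real_,
      family_size = as.integer(fam_sizes[[m$family]]),
      conservation = mirna_conservation(m$mature_seq, bundle$species),
      methylcytosine_density = track_density(iv,
                                             bundle$tracks$methylation),
      polymorphic_density_pre = track_density(iv,
                                              bundle$tracks$polymorphic),
      polymorphic_density_mature = track_density(
        data.frame(chrom = m$chrom, start = m$mature_start,
                   end = m$mature_end), bundle$tracks$polymorphic),
      polymorphic_density_target = if (nrow(tg) > 0 &&
                                         any(!is.na(tg$site_gstart))) {
        tt <- tg[!is.na(tg$site_gstart), , drop = FALSE]
        mean(vapply(seq_len(nrow(tt)), function(k) {
          track_density(data.frame(chrom = tt$site_chrom[k],
                                   start = tt$site_gstart[k],
                                   end = tt$site_gend[k]),
                        bundle$tracks$polymorphic)
        }, 0))
      } else NA_real_,
      mirna_expression_mean = if (!is.null(expr_mean) &&
                                    m$id %in% names(expr_mean)) {
        unname(expr_mean[m$id])
      } else NA_real_,
      stringsAsFactors = FALSE)
  }
  if (n == 0) return(data.frame(mirna_id = character(0)))
  do.call(rbind, rows)
}

#' Regulatory-system features per miRNA group
#'
#' Target-gene copy number, alternative splice number, and the percentage
#' of targets inside segmental-duplication blocks and tandem arrays,
#' averaged per miRNA group, with the all-genes baseline.
#'
#' @param bundle annotation bundle
#' @param result classification result from [classify_bundle()]
#' @param mirna_ids miRNA ids of the group
#' @param cfg a [classify_config()]
#' @return one-row data.frame
#' @export
system_features <- function(bundle, result, mirna_ids,
                            cfg = classify_config()) {
  genes <- bundle$genes
  fams <- result$gene_families
  fam_size <- table(fams)
  arrays <- tandem_gene_arrays(fams, genes,
                               max_between = cfg$tandem_gene_gap)
  in_array <- genes$id %in% unlist(arrays)
  in_block <- rep(FALSE, nrow(genes))
  for (ch in result$chains) {
    sp <- chain_spans(ch, genes)
    for (side in sp) {
      in_block <- in_block | (genes$chrom == side$chrom &
                                genes$start >= side$start &
                                genes$end <= side$end)
    }
  }
  tgt_ids <- unique(unlist(lapply(mirna_ids, function(id) {
    result$targets[[id]]$gene_id
  })))
  gi <- match(tgt_ids, genes$id)
  gi <- gi[!is.na(gi)]
  if (length(gi) == 0) {
    return(data.frame(n_targets = 0L, target_copy_number_mean = NA_real_,
                      target_splice_number_mean = NA_real_,
                      pct_targets_in_segmental_blocks = NA_real_,
                      pct_targets_in_tandem_arrays = NA_real_))
  }
  data.frame(
    n_targets = length(gi),
    target_copy_number_mean =
      mean(as.numeric(fam_size[as.character(fams[genes$id[gi]])])),
    target_splice_number_mean = mean(genes$isoform_count[gi]),
    pct_targets_in_segmental_blocks = 100 * mean(in_block[gi]),
    pct_targets_in_tandem_arrays = 100 * mean(in_array[gi]))
}

#' Compare a feature between two groups
#'
#' Numeric features get a Welch t-test on group values; binary features a
#' chi-square test on the 2x2 group-by-state table. Degenerate inputs
#' (empty group, constant values) yield P = NA.
#'
#' @param values feature values
#' @param group logical: TRUE = group 1 (de novo), FALSE = group 2
#' @param type "numeric" or "binary"
#' @return list(mean1, mean2, p)
#' @export
compare_groups <- function(values, group, type = c("numeric", "binary")) {
  type <- match.arg(type)
  x <- values[group & !is.na(values)]
  y <- values[!group & !is.na(values)]
  if (length(x) == 0 || length(y) == 0) {
    return(list(mean1 = if (length(x)) mean(x) else NA_real_,
                mean2 = if (length(y)) mean(y) else NA_real_, p = NA_real_))
  }
  if (type == "binary") {
    tt <- chi_square_2x2(sum(x), sum(!x), sum(y), sum(!y))
    list(mean1 = mean(x), mean2 = mean(y), p = tt$p)
  } else {
    tt <- welch_t(x, y)
    list(mean1 = mean(x), mean2 = mean(y), p = tt$p)
  }
}

#' Build the de novo versus conserved comparison tables
#'
#' Group 1 (de novo) = miRNAs labelled TR, PR or ID; group 2 (conserved) =
#' TD or SD. Table 1 compares the per-miRNA feature panel row by row
#' (t-test for numeric rows, chi-square for binary rows); table 2 compares
#' the regulatory-system features of each group's target genes.
#'
#' @param bundle annotation bundle
#' @param result classification result from [classify_bundle()]
#' @param features feature panel from [compute_features()]
#' @param cfg a [classify_config()]
#' @return list(table1, table2, groups)
#' @export
build_tables <- function(bundle, result, features,
                         cfg = classify_config()) {
  m <- label_matrix(result$calls)
  de_novo <- m[, "TR"] | m[, "PR"] | m[, "ID"]
  conserved <- (m[, "TD"] | m[, "SD"]) & !de_novo
  idx <- match(result$calls$mirna_id, features$mirna_id)
  binary_rows <- c("first_nt_is_A", "multi_mirna", "genic_location")
  skip <- "mirna_id"
  rows <- setdiff(names(features), skip)
  grp <- rep(NA, nrow(features))
  grp[idx[de_novo]] <- TRUE
  grp[idx[conserved]] <- FALSE
  tab1 <- do.call(rbind, lapply(rows, function(rn) {
    v <- features[[rn]]
    keep <- !is.na(grp)
    cc <- compare_groups(v[keep], grp[keep],
                         if (rn %in% binary_rows) "binary" else "numeric")
    data.frame(feature = rn, de_novo = cc$mean1, conserved = cc$mean2,
               p = cc$p, stringsAsFactors = FALSE)
  }))
  ids_dn <- result$calls$mirna_id[de_novo]
  ids_cv <- result$calls$mirna_id[conserved]
  sys_dn <- system_features(bundle, result, ids_dn, cfg)
  sys_cv <- system_features(bundle, result, ids_cv, cfg)
  sys_all <- all_gene_system_baseline(bundle, result, cfg)
  tab2 <- data.frame(
    feature = c("copy_number", "splice_number", "pct_segmental",
                "pct_tandem"),
    de_novo = c(sys_dn$target_copy_number_mean,
                sys_dn$target_splice_number_mean,
                sys_dn$pct_targets_in_segmental_blocks,
                sys_dn$pct_targets_in_tandem_arrays),
    conserved = c(sys_cv$target_copy_number_mean,
                  sys_cv$target_splice_number_mean,
                  sys_cv$pct_targets_in_segmental_blocks,
                  sys_cv$pct_targets_in_tandem_arrays),
    all_genes = c(sys_all$copy_number, sys_all$splice_number,
                  sys_all$pct_segmental, sys_all$pct_tandem),
    stringsAsFactors = FALSE)
  list(table1 = tab1, table2 = tab2,
       groups = list(de_novo = ids_dn, conserved = ids_cv))
}

all_gene_system_baseline <- function(bundle, result, cfg) {
  genes <- bundle$genes
  if (nrow(genes) == 0) {
    return(list(copy_number = NA_real_, splice_number = NA_real_,
                pct_segmental = NA_real_, pct_tandem = NA_real_))
  }
  fams <- result$gene_families
  fam_size <- table(fams)
  arrays <- tandem_gene_arrays(fams, genes,
                               max_between = cfg$tandem_gene_gap)
  in_array <- genes$id %in% unlist(arrays)
  in_block <- rep(FALSE, nrow(genes))
  for (ch in result$chains) {
    sp <- chain_spans(ch, genes)
    for (side in sp) {
      in_block <- in_block | (genes$chrom == side$chrom &
                                genes$start >= side$start &
                                genes$end <= side$end)
    }
  }
  list(copy_number = mean(as.numeric(fam_size[as.character(fams[genes$id])])),
       splice_number = mean(genes$isoform_count),
       pct_segmental = 100 * mean(in_block),
       pct_tandem = 100 * mean(in_array))
}
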
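# Synthetic genome generator.
#
# Emits a small one-chromosome genome plus every annotation file the
# pipeline consumes, with planted miRNA origin mechanisms and a truth
# table, so the full pipeline is testable without external data.
#
# Planted mechanisms:
#   A  two adjacent inverted copies of a long non-MITE repeat form a
#      foldback; the repeat also sits inside a target gene's transcript
#   B  a MITE (terminal inverted repeats, palindromic core) is itself the
#      foldback; an identical-family MITE copy sits inside a target gene
#   C  two adjacent inverted pseudogene copies of one parent gene
#   D  two adjacent pseudogene copies from two paralogous parents
# plus tandem miRNA pairs, collinear segmental blocks with a miRNA pair,
# and background ("other") hairpins.
#
# Background sequence is i.i.d. uniform over {A,C,G,T}: the simplest null
# that cannot fake homology. One genome = one chromosome ("chr1").

DNA_BASES <- c("A", "C", "G", "T")
AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

rand_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

rand_protein <- function(n) {
  paste(sample(AA_LETTERS, n, replace = TRUE), collapse = "")
}

# substitute a binomially sampled number of sites; each mutated site gets a
# uniformly chosen different letter; returns string with attr "n_sub"
mutate_seq <- function(seq, rate, alphabet = DNA_BASES) {
  v <- strsplit(seq, "")[[1]]
  n <- length(v)
  k <- stats::rbinom(1, n, rate)
  if (k > 0) {
    pos <- sample.int(n, k)
    v[pos] <- vapply(v[pos], function(b) {
      sample(setdiff(alphabet, b), 1)
    }, "")
  }
  out <- paste(v, collapse = "")
  attr(out, "n_sub") <- k
  out
}

#' Synthetic genome configuration
#'
#' Counts are numbers of planted miRNA genes per category; tandem and
#' segmental counts are taken in pairs (an odd count is rounded down).
#' Defaults give 10 plants per mechanism at 2 percent substitution
#' divergence between duplicate copies, a 400 kb chromosome, 60 background
#' coding genes and a 25 percent repeat fraction, half of it MITEs.
#'
#' @param genome_length chromosome length in bp (planted content must fit)
#' @param n_nonmite_id,n_mite_id,n_pseudo_same,n_pseudo_paralog counts for
#'   mechanisms A-D
#' @param n_tandem,n_segmental,n_background further category counts
#' @param n_coding_genes background protein-coding genes
#' @param te_fraction target proportion of the genome annotated as repeats
#' @param mite_fraction proportion of background repeats that are MITEs
#' @param mutation_rate substitution probability per site applied to each
#'   planted duplicate copy
#' @param seed random seed (same config + seed gives byte-identical output)
#' @param mircheck_validate regenerate planted foldbacks until they pass
#'   the MIRcheck-style filter (up to `max_retries`); disable to study
#'   degraded plants
#' @param max_retries bounded retry count per planted locus
#' @return validated list of class `synth_config`
#' @export
synth_config <- function(genome_length = 400000L,
                         n_nonmite_id = 10L, n_mite_id = 10L,
                         n_pseudo_same = 10L, n_pseudo_paralog = 10L,
                         n_tandem = 10L, n_segmental = 10L,
                         n_background = 10L, n_coding_genes = 60L,
                         te_fraction = 0.25, mite_fraction = 0.5,
                         mutation_rate = 0.02, seed = 1L,
                         mircheck_validate = TRUE, max_retries = 20L) {
  cfg <- list(genome_length = as.integer(genome_length),
              n_nonmite_id = as.integer(n_nonmite_id),
              n_mite_id = as.integer(n_mite_id),
              n_pseudo_same = as.integer(n_pseudo_same),
              n_pseudo_paralog = as.integer(n_pseudo_paralog),
              n_tandem = as.integer(n_tandem),
              n_segmental = as.integer(n_segmental),
              n_background = as.integer(n_background),
              n_coding_genes = as.integer(n_coding_genes),
              te_fraction = te_fraction, mite_fraction = mite_fraction,
              mutation_rate = mutation_rate, seed = as.integer(seed),
              mircheck_validate = isTRUE(mircheck_validate),
              max_retries = as.integer(max_retries))
  counts <- unlist(cfg[grep("^n_", names(cfg))])
  if (any(counts < 0)) stop("counts must be >= 0")
  if (te_fraction < 0 || te_fraction > 1 || mite_fraction < 0 ||
      mite_fraction > 1) stop("fractions must be in [0, 1]")
  if (mutation_rate < 0 || mutation_rate > 1) {
    stop("mutation_rate must be in [0, 1]")
  }
  class(cfg) <- "synth_config"
  cfg
}

#' Plant an inverted repeat pair (foldback locus)
#'
#' The locus is an independently mutated copy of the source, a spacer, and
#' the reverse complement of a second independently mutated copy. The two
#' arms' similarity is 1 minus the observed substitution divergence between
#' the copies.
#'
#' @param source_seq source sequence, >= 60 nt
#' @param spacer_len spacer (future loop) length, >= 3 nt
#' @param mutation_rate per-site substitution probability per copy
#' @return list: locus (sequence), copy1, copy2 (mutated copies, copy2
#'   before reverse complementing), spacer, arm_similarity
#' @export
plant_inverted_repeat_pair <- function(source_seq, spacer_len = 6L,
                                       mutation_rate = 0) {
  if (nchar(source_seq) < 60) stop("source sequence too short (< 60 nt)")
  if (spacer_len < 3) stop("spacer_len must be >= 3")
  c1 <- mutate_seq(source_seq, mutation_rate)
  c2 <- mutate_seq(source_seq, mutation_rate)
  spacer <- rand_dna(spacer_len)
  list(locus = paste0(c1, spacer, revcomp(c2)),
       copy1 = as.character(c1), copy2 = as.character(c2), spacer = spacer,
       n_sub1 = attr(c1, "n_sub"), n_sub2 = attr(c2, "n_sub"),
       arm_similarity = hamming_identity(as.character(c1), as.character(c2)))
}

# --- builder -------------------------------------------------------------

new_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$chunks <- list()
  env$pos <- 0L
  env$mirnas <- list()
  env$repeats <- list()
  env$pseudogenes <- list()
  env$genes <- list()
  env$truth <- list()
  env$sirna <- list()
  env$promoters <- list()
  env$methylation <- list()
  env$polymorphic <- list()
  env
}

add_seq <- function(env, seq) {
  start <- env$pos
  env$chunks[[length(env$chunks) + 1L]] <- seq
  env$pos <- env$pos + nchar(seq)
  start
}

add_bg <- function(env, len) add_seq(env, rand_dna(len))

add_repeat <- function(env, start, end, strand, family, repeat_class,
                       divergence) {
  env$repeats[[length(env$repeats) + 1L]] <- data.frame(
    chrom = "chr1", start = start, end = end, strand = strand,
    family = family, repeat_class = repeat_class, divergence = divergence,
    score = 1000L, is_mite = is_mite_class(repeat_class),
    stringsAsFactors = FALSE)
}

add_mirna <- function(env, id, start, end, family, mature_rel,
                      mature_len = 21L) {
  env$mirnas[[length(env$mirnas) + 1L]] <- data.frame(
    id = id, chrom = "chr1", start = start, end = end, strand = "+",
    family = family, mature_start = start + mature_rel,
    mature_end = start + mature_rel + mature_len, n_mature = 1L,
    stringsAsFactors = FALSE)
}

add_gene <- function(env, id, cdna, protein, isoform_count = NULL) {
  if (is.null(isoform_count)) isoform_count <- sample(1:3, 1)
  start <- add_seq(env, cdna)
  env$genes[[length(env$genes) + 1L]] <- data.frame(
    id = id, chrom = "chr1", start = start, end = start + nchar(cdna),
    strand = "+", isoform_count = isoform_count, cdna_seq = cdna,
    protein_seq = protein, stringsAsFactors = FALSE)
  start
}

add_truth <- function(env, id, origin, mechanism, target) {
  env$truth[[length(env$truth) + 1L]] <- data.frame(
    mirna_id = id, true_origin = origin, true_mechanism = mechanism,
    planted_target_gene = target, stringsAsFactors = FALSE)
}

# build a foldback precursor until it passes the MIRcheck filter
attempt_plant <- function(make, mechanism, cfg) {
  tries <- if (cfg$mircheck_validate) cfg$max_retries else 1L
  for (i in seq_len(tries)) {
    unit <- make()
    if (!cfg$mircheck_validate) return(unit)
    f <- fold(unit$precursor)
    v <- mircheck(f, unit$mature_rel, unit$mature_len)
    if (v$pass) return(unit)
  }
  stop("could not plant a MIRcheck-valid hairpin for mechanism ", mechanism,
       " after ", cfg$max_retries, " attempts (mutation_rate too high?)")
}

# standard planted geometry: 90 nt arms, 6 nt spacer, mature on the 3' arm
PLANT_ARM <- 90L
PLANT_SPACER <- 6L
PLANT_MAT_OFF <- PLANT_ARM + PLANT_SPACER + 15L   # 0-based, in precursor
PLANT_MAT_LEN <- 21L

make_foldback <- function(source_arm, rate) {
  p <- plant_inverted_repeat_pair(source_arm, PLANT_SPACER, rate)
  list(precursor = p$locus, mature_rel = PLANT_MAT_OFF,
       mature_len = PLANT_MAT_LEN, plant = p)
}

# --- generator -----------------------------------------------------------

#' Generate a synthetic annotated genome bundle
#'
#' Writes genome.fa, mirna.gff3, repeats.tsv, pseudogenes.tsv, genes.gff3,
#' cdna.fa, protein.fa, tracks/*.bed, expression.tsv, species/*.fa,
#' truth.tsv and config.yaml into `out_dir` and returns the loaded bundle.
#' Identical config (including seed) gives byte-identical files.
#'
#' @param config a [synth_config()]
#' @param out_dir output directory (created if needed)
#' @return the bundle, as read back by [read_bundle()]
#' @export
generate_genome <- function(config = synth_config(), out_dir) {
  stopifnot(inherits(config, "synth_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "tracks"), showWarnings = FALSE)
  withr::with_seed(config$seed, generate_genome_impl(config, out_dir))
  read_bundle(out_dir)
}

generate_genome_impl <- function(cfg, out_dir) {
  env <- new_builder()
  rate <- cfg$mutation_rate
  pending_genes <- list()   # target/parent genes to emit in the main phase
  sd_pairs <- cfg$n_segmental %/% 2L
  td_pairs <- cfg$n_tandem %/% 2L

  # --- segmental block, first copy (region X) ---
  sd_x <- list()
  for (p in seq_len(sd_pairs)) {
    add_bg(env, 300L)
    genes <- list()
    mir_unit <- NULL
    for (k in 1:4) {
      cdna <- rand_dna(sample(450:600, 1))
      prot <- rand_protein(sample(220:280, 1))
      add_bg(env, 150L)
      add_gene(env, sprintf("sdxg%02d_%d", p, k), cdna, prot)
      genes[[k]] <- list(cdna = cdna, prot = prot)
      if (k == 2) {
        add_bg(env, 150L)
        mir_unit <- attempt_plant(function() {
          make_foldback(rand_dna(PLANT_ARM), rate)
        }, "segmental", cfg)
        s <- add_seq(env, mir_unit$precursor)
        id <- sprintf("mirSD%02da", p)
        add_mirna(env, id, s, s + nchar(mir_unit$precursor),
                  sprintf("famSD%02d", p), mir_unit$mature_rel)
        add_truth(env, id, "SD", "none", NA)
      }
    }
    sd_x[[p]] <- list(genes = genes, precursor = mir_unit$precursor,
                      mature_rel = mir_unit$mature_rel)
  }

  # --- mechanism A: non-MITE inverted duplication ---
  for (i in seq_len(cfg$n_nonmite_id)) {
    rep_len <- sample(800:1200, 1)
    R <- rand_dna(rep_len)
    unit <- attempt_plant(function() {
      p <- plant_inverted_repeat_pair(R, PLANT_SPACER, rate)
      list(precursor = paste0(
             substring(p$copy1, rep_len - PLANT_ARM + 1L, rep_len),
             p$spacer,
             substring(revcomp(p$copy2), 1L, PLANT_ARM)),
           mature_rel = PLANT_MAT_OFF, mature_len = PLANT_MAT_LEN,
           plant = p)
    }, "A (non-MITE inverted duplication)", cfg)
    p <- unit$plant
    add_bg(env, sample(400:900, 1))
    locus_start <- add_seq(env, p$locus)
    fam <- sprintf("nmA%02d", i)
    add_repeat(env, locus_start, locus_start + rep_len, "+", fam,
               "LTR/Gypsy", round(100 * p$n_sub1 / rep_len, 2))
    add_repeat(env, locus_start + rep_len + PLANT_SPACER,
               locus_start + 2L * rep_len + PLANT_SPACER, "-", fam,
               "LTR/Gypsy", round(100 * p$n_sub2 / rep_len, 2))
    pre_start <- locus_start + rep_len - PLANT_ARM
    id <- sprintf("mirA%02d", i)
    add_mirna(env, id, pre_start, pre_start + nchar(unit$precursor),
              sprintf("famA%02d", i), unit$mature_rel)
    tgt <- sprintf("tgtA%02d", i)
    insert <- as.character(mutate_seq(
      substring(R, rep_len - 199L, rep_len), rate))
    pending_genes[[length(pending_genes) + 1L]] <- list(
      id = tgt, cdna = paste0(rand_dna(150), insert, rand_dna(150)),
      prot = rand_protein(160), repeat_in = list(
        offset = 150L, len = 200L, family = fam, class = "LTR/Gypsy"))
    add_truth(env, id, "TR", "A", tgt)
  }

  # --- mechanism B: MITE-mediated ---
  for (i in seq_len(cfg$n_mite_id)) {
    tir <- rand_dna(12)
    core <- rand_dna(70)
    loop <- rand_dna(PLANT_SPACER)
    mite_src <- paste0(tir, core, loop, revcomp(core), revcomp(tir))
    mite_len <- nchar(mite_src)
    unit <- attempt_plant(function() {
      copy <- mutate_seq(mite_src, rate)
      list(precursor = as.character(copy),
           mature_rel = 12L + 70L + PLANT_SPACER + 15L,
           mature_len = PLANT_MAT_LEN, n_sub = attr(copy, "n_sub"))
    }, "B (MITE)", cfg)
    add_bg(env, sample(400:900, 1))
    s <- add_seq(env, unit$precursor)
    fam <- sprintf("miteB%02d", i)
    add_repeat(env, s, s + mite_len, "+", fam, "DNA/Stowaway",
               round(100 * unit$n_sub / mite_len, 2))
    id <- sprintf("mirB%02d", i)
    add_mirna(env, id, s, s + mite_len, sprintf("famB%02d", i),
              unit$mature_rel)
    tgt <- sprintf("tgtB%02d", i)
    pending_genes[[length(pending_genes) + 1L]] <- list(
      id = tgt,
      cdna = paste0(rand_dna(150), as.character(mutate_seq(mite_src, rate)),
                    rand_dna(150)),
      prot = rand_protein(160),
      repeat_in = list(offset = 150L, len = mite_len, family = fam,
                       class = "DNA/Stowaway"))
    add_truth(env, id, "TR", "B", tgt)
  }

  # --- mechanism C: two inverted pseudogenes of one parent ---
  for (i in seq_len(cfg$n_pseudo_same)) {
    parent_cdna <- rand_dna(600)
    seg <- substring(parent_cdna, 151, 390)   # 240 bp pseudogene source
    unit <- attempt_plant(function() {
      p <- plant_inverted_repeat_pair(seg, PLANT_SPACER, rate)
      list(precursor = paste0(
             substring(p$copy1, 240L - PLANT_ARM + 1L, 240L), p$spacer,
             substring(revcomp(p$copy2), 1L, PLANT_ARM)),
           mature_rel = PLANT_MAT_OFF, mature_len = PLANT_MAT_LEN,
           plant = p)
    }, "C (pseudogenes, one parent)", cfg)
    p <- unit$plant
    add_bg(env, sample(400:900, 1))
    locus_start <- add_seq(env, p$locus)
    parent <- sprintf("parC%02d", i)
    env$pseudogenes[[length(env$pseudogenes) + 1L]] <- data.frame(
      id = sprintf("psiC%02da", i), chrom = "chr1", start = locus_start,
      end = locus_start + 240L, strand = "+", parent_gene = parent,
      stringsAsFactors = FALSE)
    env$pseudogenes[[length(env$pseudogenes) + 1L]] <- data.frame(
      id = sprintf("psiC%02db", i), chrom = "chr1",
      start = locus_start + 240L + PLANT_SPACER,
      end = locus_start + 480L + PLANT_SPACER, strand = "-",
      parent_gene = parent, stringsAsFactors = FALSE)
    pre_start <- locus_start + 240L - PLANT_ARM
    id <- sprintf("mirC%02d", i)
    add_mirna(env, id, pre_start, pre_start + nchar(unit$precursor),
              sprintf("famC%02d", i), unit$mature_rel)
    pending_genes[[length(pending_genes) + 1L]] <- list(
      id = parent, cdna = parent_cdna, prot = rand_protein(170))
    add_truth(env, id, "PR", "C", parent)
  }

  # --- mechanism D: two pseudogenes from paralogous parents ---
  for (i in seq_len(cfg$n_pseudo_paralog)) {
    cdna1 <- rand_dna(600)
    prot1 <- rand_protein(170)
    cdna2 <- as.character(mutate_seq(cdna1, 0.04))
    prot2 <- as.character(mutate_seq(prot1, 0.05, AA_LETTERS))
    seg1 <- substring(cdna1, 151, 390)
    seg2 <- substring(cdna2, 151, 390)
    unit <- attempt_plant(function() {
      p1 <- as.character(mutate_seq(seg1, rate))
      p2 <- as.character(mutate_seq(seg2, rate))
      spacer <- rand_dna(PLANT_SPACER)
      list(precursor = paste0(substring(p1, 240L - PLANT_ARM + 1L, 240L),
                              spacer,
                              substring(revcomp(p2), 1L, PLANT_ARM)),
           mature_rel = PLANT_MAT_OFF, mature_len = PLANT_MAT_LEN,
           locus = paste0(p1, spacer, revcomp(p2)))
    }, "D (pseudogenes, paralogous parents)", cfg)
    add_bg(env, sample(400:900, 1))
    locus_start <- add_seq(env, unit$locus)
    par1 <- sprintf("parD%02da", i)
    par2 <- sprintf("parD%02db", i)
    env$pseudogenes[[length(env$pseudogenes) + 1L]] <- data.frame(
      id = sprintf("psiD%02da", i), chrom = "chr1", start = locus_start,
      end = locus_start + 240L, strand = "+", parent_gene = par1,
      stringsAsFactors = FALSE)
    env$pseudogenes[[length(env$pseudogenes) + 1L]] <- data.frame(
      id = sprintf("psiD%02db", i), chrom = "chr1",
      start = locus_start + 240L + PLANT_SPACER,
      end = locus_start + 480L + PLANT_SPACER, strand = "-",
      parent_gene = par2, stringsAsFactors = FALSE)
    pre_start <- locus_start + 240L - PLANT_ARM
    id <- sprintf("mirD%02d", i)
    add_mirna(env, id, pre_start, pre_start + nchar(unit$precursor),
              sprintf("famD%02d", i), unit$mature_rel)
    pending_genes[[length(pending_genes) + 1L]] <- list(
      id = par1, cdna = cdna1, prot = prot1)
    pending_genes[[length(pending_genes) + 1L]] <- list(
      id = par2, cdna = cdna2, prot = prot2)
    add_truth(env, id, "PR", "D", par2)
  }

  # --- tandem pairs ---
  for (p in seq_len(td_pairs)) {
    unit1 <- attempt_plant(function() {
      make_foldback(rand_dna(PLANT_ARM), rate)
    }, "tandem", cfg)
    unit2 <- attempt_plant(function() {
      list(precursor = as.character(mutate_seq(unit1$precursor, rate)),
           mature_rel = unit1$mature_rel, mature_len = unit1$mature_len)
    }, "tandem", cfg)
    fam <- sprintf("famTD%02d", p)
    add_bg(env, sample(400:900, 1))
    s1 <- add_seq(env, unit1$precursor)
    id1 <- sprintf("mirTD%02da", p)
    add_mirna(env, id1, s1, s1 + nchar(unit1$precursor), fam,
              unit1$mature_rel)
    add_bg(env, sample(2000:8000, 1))
    s2 <- add_seq(env, unit2$precursor)
    id2 <- sprintf("mirTD%02db", p)
    add_mirna(env, id2, s2, s2 + nchar(unit2$precursor), fam,
              unit2$mature_rel)
    add_truth(env, id1, "TD", "none", NA)
    add_truth(env, id2, "TD", "none", NA)
  }

  # --- background miRNAs (other) ---
  for (i in seq_len(cfg$n_background)) {
    unit <- attempt_plant(function() {
      make_foldback(rand_dna(PLANT_ARM), rate)
    }, "background", cfg)
    add_bg(env, sample(400:900, 1))
    s <- add_seq(env, unit$precursor)
    id <- sprintf("mirBG%02d", i)
    add_mirna(env, id, s, s + nchar(unit$precursor),
              sprintf("famBG%02d", i), unit$mature_rel)
    add_truth(env, id, "OT", "none", NA)
  }

  # --- main-phase genes: planted targets/parents striped with background ---
  bg_gene_specs <- lapply(seq_len(cfg$n_coding_genes), function(i) {
    list(id = sprintf("gene%03d", i), cdna = rand_dna(sample(450:750, 1)),
         prot = rand_protein(sample(140:220, 1)))
  })
  all_specs <- list()
  na <- max(length(pending_genes), length(bg_gene_specs))
  for (i in seq_len(na)) {
    if (i <= length(pending_genes)) {
      all_specs[[length(all_specs) + 1L]] <- pending_genes[[i]]
    }
    if (i <= length(bg_gene_specs)) {
      all_specs[[length(all_specs) + 1L]] <- bg_gene_specs[[i]]
    }
  }
  for (gs in all_specs) {
    add_bg(env, sample(200:600, 1))
    gstart <- add_gene(env, gs$id, gs$cdna, gs$prot)
    if (!is.null(gs$repeat_in)) {
      add_repeat(env, gstart + gs$repeat_in$offset,
                 gstart + gs$repeat_in$offset + gs$repeat_in$len, "+",
                 gs$repeat_in$family, gs$repeat_in$class,
                 round(100 * cfg$mutation_rate, 2))
    }
  }

  # --- segmental block, second copy (region Y) ---
  add_bg(env, 2000L)
  for (p in seq_len(sd_pairs)) {
    add_bg(env, 300L)
    for (k in 1:4) {
      g <- sd_x[[p]]$genes[[k]]
      add_bg(env, 150L)
      add_gene(env, sprintf("sdyg%02d_%d", p, k),
               as.character(mutate_seq(g$cdna, 0.04)),
               as.character(mutate_seq(g$prot, 0.05, AA_LETTERS)))
      if (k == 2) {
        add_bg(env, 150L)
        unit <- attempt_plant(function() {
          list(precursor = as.character(
                 mutate_seq(sd_x[[p]]$precursor, rate)),
               mature_rel = sd_x[[p]]$mature_rel,
               mature_len = PLANT_MAT_LEN)
        }, "segmental", cfg)
        s <- add_seq(env, unit$precursor)
        id <- sprintf("mirSD%02db", p)
        add_mirna(env, id, s, s + nchar(unit$precursor),
                  sprintf("famSD%02d", p), unit$mature_rel)
        add_truth(env, id, "SD", "none", NA)
      }
    }
  }

  # --- pad to genome_length, carving background repeat annotations ---
  assembled <- env$pos
  if (assembled > cfg$genome_length) {
    stop("genome_length (", cfg$genome_length, ") too small for planted ",
         "content (", assembled, " bp); increase genome_length")
  }
  pad <- cfg$genome_length - assembled
  planted_te_bp <- if (length(env$repeats)) {
    sum(vapply(env$repeats, function(r) r$end - r$start, 0L))
  } else 0L
  te_target <- max(0, round(cfg$te_fraction * cfg$genome_length) -
                        planted_te_bp)
  nonmite_classes <- c("LTR/Gypsy", "LTR/Copia", "DNA/hAT", "LINE/L1")
  pad_start <- env$pos
  if (pad > 0) add_bg(env, pad)
  cursor <- pad_start + 200L
  te_done <- 0
  i_te <- 0L
  while (te_done < te_target && cursor + 3500L < cfg$genome_length - 200L) {
    len <- sample(500:3000, 1)
    i_te <- i_te + 1L
    mite <- stats::runif(1) < cfg$mite_fraction
    cls <- if (mite) sample(c("DNA/Stowaway", "DNA/Tourist"), 1) else {
      sample(nonmite_classes, 1)
    }
    add_repeat(env, cursor, cursor + len, sample(c("+", "-"), 1),
               sprintf("bgTE%04d", i_te), cls,
               round(stats::runif(1, 2, 30), 2))
    te_done <- te_done + len
    cursor <- cursor + len + sample(200:800, 1)
  }

  # --- assemble tables ---
  genome <- stats::setNames(paste(unlist(env$chunks), collapse = ""), "chr1")
  bind <- function(lst, template) {
    if (length(lst)) do.call(rbind, lst) else template
  }
  mirnas <- bind(env$mirnas, data.frame(
    id = character(0), chrom = character(0), start = integer(0),
    end = integer(0), strand = character(0), family = character(0),
    mature_start = integer(0), mature_end = integer(0),
    n_mature = integer(0)))
  repeats <- bind(env$repeats, data.frame(
    chrom = character(0), start = integer(0), end = integer(0),
    strand = character(0), family = character(0),
    repeat_class = character(0), divergence = numeric(0), score = integer(0),
    is_mite = logical(0)))
  pseudogenes <- bind(env$pseudogenes, data.frame(
    id = character(0), chrom = character(0), start = integer(0),
    end = integer(0), strand = character(0), parent_gene = character(0)))
  genes <- bind(env$genes, data.frame(
    id = character(0), chrom = character(0), start = integer(0),
    end = integer(0), strand = character(0), isoform_count = integer(0),
    cdna_seq = character(0), protein_seq = character(0)))
  truth <- bind(env$truth, data.frame(
    mirna_id = character(0), true_origin = character(0),
    true_mechanism = character(0), planted_target_gene = character(0)))

  # --- tracks ---
  tracks <- synth_tracks(mirnas, truth, genes)

  # --- species catalogs: conserved (TD/SD) matures recur in 3 species ---
  species <- list(spA = character(0), spB = character(0), spC = character(0))
  conserved <- truth$mirna_id[truth$true_origin %in% c("TD", "SD")]
  for (id in conserved) {
    r <- mirnas[mirnas$id == id, ]
    mat <- substring(genome, r$mature_start + 1L, r$mature_end)
    for (sp in names(species)) {
      species[[sp]][paste0(sp, "_", id)] <-
        as.character(mutate_seq(mat, 0.03))
    }
  }

  # --- expression ---
  ids <- c(genes$id, mirnas$id)
  expression <- if (length(ids)) {
    data.frame(id = ids,
               expr1 = round(stats::rlnorm(length(ids), 4, 1), 2),
               expr2 = round(stats::rlnorm(length(ids), 4, 1), 2),
               expr3 = round(stats::rlnorm(length(ids), 4, 1), 2),
               stringsAsFactors = FALSE)
  } else {
    data.frame(id = character(0), expr1 = numeric(0), expr2 = numeric(0),
               expr3 = numeric(0))
  }

  # --- write bundle ---
  p <- function(...) file.path(out_dir, ...)
  write_genome(genome, p("genome.fa"))
  write_mirna_gff3(mirnas, p("mirna.gff3"))
  write_repeat_table(repeats, p("repeats.tsv"))
  write_pseudogene_table(pseudogenes, p("pseudogenes.tsv"))
  write_gene_gff3(genes, p("genes.gff3"))
  write_genome(stats::setNames(genes$cdna_seq, genes$id), p("cdna.fa"))
  aa <- Biostrings::AAStringSet(stats::setNames(genes$protein_seq, genes$id))
  Biostrings::writeXStringSet(aa, p("protein.fa"), width = 60L)
  for (tr in names(tracks)) write_bed(tracks[[tr]], p("tracks",
                                                      paste0(tr, ".bed")))
  utils::write.table(expression, p("expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (any(lengths(species) > 0)) {
    dir.create(p("species"), showWarnings = FALSE)
    for (sp in names(species)) {
      if (length(species[[sp]])) {
        write_genome(species[[sp]], p("species", paste0(sp, ".fa")))
      }
    }
  }
  utils::write.table(truth, p("truth.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  yaml::write_yaml(unclass(cfg), p("config.yaml"))
  invisible(NULL)
}

# per-miRNA tracks: siRNAs in precursors, TATA promoters upstream,
# methylation / polymorphism denser in de novo plants than conserved ones
synth_tracks <- function(mirnas, truth, genes) {
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      score = integer(0), strand = character(0))
  tracks <- list(sirna = empty, promoters = empty, methylation = empty,
                 polymorphic = empty)
  if (nrow(mirnas) == 0) return(tracks)
  de_novo_ids <- truth$mirna_id[truth$true_origin %in% c("TR", "PR")]
  si <- list(); pr <- list(); me <- list(); po <- list()
  for (i in seq_len(nrow(mirnas))) {
    r <- mirnas[i, ]
    len <- r$end - r$start
    dn <- r$id %in% de_novo_ids
    nsi <- stats::rpois(1, if (dn) 1.5 else 0.4)
    for (k in seq_len(nsi)) {
      off <- sample.int(max(1L, len - 24L), 1)
      si[[length(si) + 1L]] <- data.frame(
        chrom = r$chrom, start = r$start + off, end = r$start + off + 24L,
        name = sprintf("si_%s_%d", r$id, k), score = 0L, strand = "+")
    }
    if (stats::runif(1) < (if (dn) 0.4 else 0.8)) {
      up <- max(0L, r$start - sample(100:900, 1))
      pr[[length(pr) + 1L]] <- data.frame(
        chrom = r$chrom, start = up, end = up + 8L,
        name = sprintf("tata_%s", r$id), score = 0L, strand = "+")
    }
    dens_me <- if (dn) 0.03 else 0.004
    dens_po <- if (dn) 0.04 else 0.01
    for (pos in which(stats::runif(len) < dens_me)) {
      me[[length(me) + 1L]] <- data.frame(
        chrom = r$chrom, start = r$start + pos - 1L, end = r$start + pos,
        name = "mC", score = 0L, strand = "+")
    }
    for (pos in which(stats::runif(len) < dens_po)) {
      po[[length(po) + 1L]] <- data.frame(
        chrom = r$chrom, start = r$start + pos - 1L, end = r$start + pos,
        name = "snp", score = 0L, strand = "+")
    }
  }
  if (length(si)) tracks$sirna <- do.call(rbind, si)
  if (length(pr)) tracks$promoters <- do.call(rbind, pr)
  if (length(me)) tracks$methylation <- do.call(rbind, me)
  if (length(po)) tracks$polymorphic <- do.call(rbind, po)
  tracks
}
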
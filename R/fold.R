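# Hairpin secondary structure: maximum base-pairing fold plus the
# MIRcheck-style precursor validity criteria and structural measurements.
#
# The folding engine is a Nussinov-style dynamic program maximising the
# number of nested pairs over {AU, GC, GU} with a minimum loop of 3 nt. It
# substitutes for a thermodynamic folder: the downstream criteria count
# pairings, not energies. This is a documented fidelity gap.

#' Fold a sequence into its maximum base-pairing nested structure
#'
#' @param seq nucleotide string over A, C, G, U/T, N (N never pairs)
#' @param min_loop minimum hairpin loop size in nt (default 3)
#' @return an object of class `hairpin_fold`: list with `seq`, `n`,
#'   `pair_table` (1-based partner index per position, 0 = unpaired) and
#'   `n_pairs`
#' @export
fold <- function(seq, min_loop = 3L) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < 5) stop("sequence too short to fold (need >= 5 nt)")
  if (grepl("[^ACGUTN]", seq)) stop("sequence has characters outside ACGUTN")
  pt <- nussinov_pair_table(seq, as.integer(min_loop))
  structure(list(seq = seq, n = n, pair_table = pt,
                 n_pairs = sum(pt > 0) %/% 2L),
            class = "hairpin_fold")
}

#' Dot-bracket string of a fold
#' @param fold a `hairpin_fold`
#' @return character scalar
#' @export
dot_bracket <- function(fold) {
  pt <- fold$pair_table
  ch <- rep(".", fold$n)
  ch[pt > 0 & seq_along(pt) < pt] <- "("
  ch[pt > 0 & seq_along(pt) > pt] <- ")"
  paste(ch, collapse = "")
}

# hairpin loops: pairs (i, j) enclosing no other paired position
hairpin_loops <- function(fold) {
  pt <- fold$pair_table
  ij <- which(pt > seq_along(pt))
  loops <- list()
  for (i in ij) {
    j <- pt[i]
    if (j - i >= 2 && all(pt[(i + 1):(j - 1)] == 0)) {
      loops[[length(loops) + 1]] <- c(start = i + 1L, end = j - 1L)
    }
  }
  loops
}

# choose the hairpin loop nearest the mature span (or the first by position)
choose_loop <- function(fold, mature_span = NULL) {
  loops <- hairpin_loops(fold)
  if (length(loops) == 0) return(NULL)
  if (is.null(mature_span)) return(loops[[1]])
  mid <- mean(mature_span)
  d <- vapply(loops, function(l) min(abs(l - mid)), 0)
  loops[[which.min(d)]]
}

#' MIRcheck-style precursor verdict
#'
#' A precursor passes when the mature and its inferred miRNA* each have
#' at most `max_mismatch` mismatches, at most `max_consecutive` consecutive
#' mismatches, and the mature has at most `max_asymmetric` asymmetrically
#' unpaired nucleotides. A "mismatch" is a position that is unpaired or
#' paired outside the partner span; the miRNA* is the paired span of the
#' mature with the canonical 2-nt 3' offset; asymmetric unpaired positions
#' are unpaired mature positions in excess of unpaired miRNA* positions.
#' A mature spanning the loop fails with a reason rather than erroring.
#'
#' @param fold a `hairpin_fold`
#' @param mature_offset 0-based offset of the mature inside the precursor
#' @param mature_len mature length (nt)
#' @param max_mismatch,max_consecutive,max_asymmetric criteria bounds
#' @return list of class `mircheck_verdict`: pass, reason, mismatches_mir,
#'   mismatches_star, max_consecutive_mismatches, asymmetric_unpaired,
#'   star_span, arm
#' @export
mircheck <- function(fold, mature_offset, mature_len,
                     max_mismatch = 4L, max_consecutive = 2L,
                     max_asymmetric = 2L) {
  stopifnot(mature_offset >= 0, mature_offset + mature_len <= fold$n)
  mat <- (mature_offset + 1L):(mature_offset + mature_len)
  fail <- function(reason) {
    structure(list(pass = FALSE, reason = reason, mismatches_mir = NA_integer_,
                   mismatches_star = NA_integer_,
                   max_consecutive_mismatches = NA_integer_,
                   asymmetric_unpaired = NA_integer_, star_span = NULL,
                   arm = NA_character_),
              class = "mircheck_verdict")
  }
  loop <- choose_loop(fold, range(mat))
  if (is.null(loop)) return(fail("no hairpin loop in fold"))
  if (any(mat >= loop["start"]) && any(mat <= loop["end"]) &&
      (min(mat) < loop["start"] && max(mat) > loop["end"])) {
    return(fail("mature spans the loop"))
  }
  if (min(mat) >= loop["start"] && max(mat) <= loop["end"]) {
    return(fail("mature inside the loop"))
  }
  arm <- if (max(mat) < loop["start"]) "5p" else "3p"
  pt <- fold$pair_table
  partners <- pt[mat]
  paired <- partners > 0
  if (!any(paired)) return(fail("mature entirely unpaired"))
  # miRNA* span: paired span of the mature, 3' end extended by the 2-nt
  # duplex overhang (the star's 3' side is at higher index on the 5' arm,
  # lower index on the 3' arm)
  # paired core of the star; reported star_span adds the 2-nt 3' overhang
  core <- c(min(partners[paired]), max(partners[paired]))
  star <- if (arm == "5p") {
    c(max(1L, core[1] - 2L), core[2])
  } else {
    c(core[1], min(fold$n, core[2] + 2L))
  }
  mm_vec_mir <- !paired | partners < star[1] | partners > star[2]
  # star mismatches are counted over the paired core: the overhang
  # positions belong to duplex geometry, not to the duplex pairing
  sp <- pt[core[1]:core[2]]
  mm_vec_star <- sp == 0 | sp < min(mat) | sp > max(mat)
  runmax <- function(v) {
    if (!any(v)) return(0L)
    r <- rle(v)
    max(r$lengths[r$values])
  }
  mm_mir <- sum(mm_vec_mir)
  mm_star <- sum(mm_vec_star)
  consec <- max(runmax(mm_vec_mir), runmax(mm_vec_star))
  asym <- max(0L, sum(!paired) - sum(sp == 0))
  pass <- mm_mir <= max_mismatch && mm_star <= max_mismatch &&
    runmax(mm_vec_mir) <= max_consecutive &&
    runmax(mm_vec_star) <= max_consecutive && asym <= max_asymmetric
  structure(list(pass = pass, reason = if (pass) "" else "criteria not met",
                 mismatches_mir = as.integer(mm_mir),
                 mismatches_star = as.integer(mm_star),
                 max_consecutive_mismatches = as.integer(consec),
                 asymmetric_unpaired = as.integer(asym),
                 star_span = as.integer(star), arm = arm),
            class = "mircheck_verdict")
}

#' Structural features of a folded precursor
#'
#' Measures the Table-style structural panel: stem length (paired positions
#' 5' of the hairpin loop), loop length, match ratio (paired positions /
#' precursor length), and the distance between the mature and the loop.
#'
#' @inheritParams mircheck
#' @return one-row data.frame: precursor_length, mirna_length, stem_length,
#'   loop_length, match_ratio, mir_loop_distance
#' @export
structural_features <- function(fold, mature_offset = NULL,
                                mature_len = NULL) {
  mat <- if (!is.null(mature_offset)) {
    (mature_offset + 1L):(mature_offset + mature_len)
  } else NULL
  loop <- choose_loop(fold, if (is.null(mat)) NULL else range(mat))
  pt <- fold$pair_table
  if (is.null(loop)) {
    loop_len <- 0L
    stem <- 0L
    mld <- NA_integer_
  } else {
    loop_len <- loop["end"] - loop["start"] + 1L
    stem <- sum(pt[seq_len(loop["start"] - 1L)] > 0)
    mld <- if (is.null(mat)) {
      NA_integer_
    } else if (max(mat) < loop["start"]) {
      loop["start"] - max(mat) - 1L
    } else if (min(mat) > loop["end"]) {
      min(mat) - loop["end"] - 1L
    } else {
      0L
    }
  }
  data.frame(precursor_length = fold$n,
             mirna_length = if (is.null(mat)) NA_integer_ else length(mat),
             stem_length = as.integer(stem),
             loop_length = as.integer(loop_len),
             match_ratio = sum(pt > 0) / fold$n,
             mir_loop_distance = as.integer(mld))
}
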
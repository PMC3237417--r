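# Local alignment, identity and E-value machinery shared by the inverted
# duplication detector, family clustering and the tandem test.

#' Default alignment scoring scheme
#' @return list(match, mismatch, gap_open, gap_extend)
#' @export
default_scoring <- function() {
  list(match = 1, mismatch = -1, gap_open = -2, gap_extend = -1)
}

#' Karlin-Altschul style E-value
#'
#' E = K * m * n * exp(-lambda * S). The constants substitute for the
#' statistics of the external search tools (which the source analyses do
#' not state); they are fixed at K = 0.1, lambda = 1.037 and overridable,
#' so thresholds are reproducible rather than tool-faithful.
#'
#' @param score raw alignment score
#' @param m,n query and subject lengths (>= 1)
#' @param K,lambda positive constants
#' @return numeric E-value
#' @export
evalue <- function(score, m, n, K = 0.1, lambda = 1.037) {
  if (K <= 0 || lambda <= 0) stop("K and lambda must be positive")
  if (any(m < 1) || any(n < 1)) stop("sequence lengths must be >= 1")
  K * m * n * exp(-lambda * score)
}

#' Smith-Waterman local alignment
#'
#' Affine gaps: a gap of length L costs gap_open + gap_extend * (L - 1)
#' (both negative). N (and X for proteins) scores as mismatch. Traceback is
#' deterministic with tie preference diagonal > up > left. Identity is
#' computed over aligned columns with each gap run counted as one column
#' (gap-compressed).
#'
#' @param query,subject sequences (nucleotide or protein)
#' @param scoring list as from [default_scoring()]
#' @param K,lambda E-value constants, see [evalue()]
#' @param wildcard character that always mismatches: "N" for nucleotides;
#'   pass "X" for proteins (where N is asparagine)
#' @return list of class `alignment_hit`: score, query_span, subject_span
#'   (1-based inclusive), matches, aligned_cols, identity, evalue
#' @export
smith_waterman <- function(query, subject, scoring = default_scoring(),
                           K = 0.1, lambda = 1.037, wildcard = "N") {
  if (!nzchar(query) || !nzchar(subject)) stop("empty input sequence")
  r <- sw_align_cpp(toupper(query), toupper(subject),
                    match = scoring$match, mismatch = scoring$mismatch,
                    gap_open = -scoring$gap_open,
                    gap_extend = -scoring$gap_extend, wildcard = wildcard)
  hit <- list(score = r$score,
              query_span = c(r$query_start, r$query_end),
              subject_span = c(r$subject_start, r$subject_end),
              matches = r$matches, aligned_cols = r$aligned_cols,
              identity = if (r$aligned_cols > 0) r$matches / r$aligned_cols
                         else 0,
              evalue = evalue(r$score, nchar(query), nchar(subject),
                              K = K, lambda = lambda))
  class(hit) <- "alignment_hit"
  hit
}

#' Global percent similarity of two copies
#'
#' Gap-compressed global identity: a Needleman-Wunsch alignment under the
#' shared scoring scheme, identity = matches / aligned columns with each
#' gap run compressed to one column. Used for the >80 percent similarity
#' test on inverted repeat copies.
#'
#' @param a,b nucleotide strings
#' @return fraction in [0, 1]
#' @export
percent_similarity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("empty input sequence")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE),
    gapOpening = 2, gapExtension = 1)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  gap <- pa == "-" | sa == "-"
  nmatch <- sum(!gap & pa == sa)
  nmis <- sum(!gap & pa != sa)
  gap_runs <- if (any(gap)) {
    r <- rle(gap)
    sum(r$values)
  } else 0L
  cols <- nmatch + nmis + gap_runs
  if (cols == 0) return(0)
  nmatch / cols
}

# fraction of identical positions between two equal-length strings
hamming_identity <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  mean(av == bv)
}
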
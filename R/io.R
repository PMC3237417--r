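# Annotation and sequence I/O.
#
# Internal coordinate convention: 0-based, half-open [start, end) on a named
# chromosome, strand "+" or "-". GFF3 and the RepeatMasker-style repeat
# table are 1-based closed on disk; BED is 0-based half-open; conversion
# happens here and nowhere else. Spans *within* a sequence string (alignment
# spans, mature offsets relative to a precursor) use R's 1-based inclusive
# substring convention, except mature_offset which is the 0-based offset of
# the mature inside the precursor.

#' Create a genomic interval table
#'
#' @param chrom chromosome name(s)
#' @param start 0-based start(s)
#' @param end end(s), exclusive
#' @param strand "+" or "-"
#' @return a data.frame with columns chrom, start, end, strand
#' @export
genomic_interval <- function(chrom, start, end, strand = "+") {
  stopifnot(all(start >= 0), all(start < end))
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             strand = strand, stringsAsFactors = FALSE)
}

#' Overlap in base pairs between two intervals
#'
#' Strand-agnostic; intervals on different chromosomes overlap by 0 bp.
#' Vectorised over rows (recycled).
#'
#' @param a,b interval data.frames as from [genomic_interval()]
#' @return integer vector of overlap lengths
#' @export
overlap_bp <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  ai <- rep_len(seq_len(nrow(a)), n)
  bi <- rep_len(seq_len(nrow(b)), n)
  ov <- pmax(0L, pmin(a$end[ai], b$end[bi]) - pmax(a$start[ai], b$start[bi]))
  ov[a$chrom[ai] != b$chrom[bi]] <- 0L
  as.integer(ov)
}

#' Reverse complement of DNA strings
#' @param x character vector of DNA sequences
#' @return character vector
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Read a genome FASTA into a named character vector
#' @param path FASTA file
#' @return named character vector, chrom -> sequence
#' @export
read_genome <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write a genome FASTA (60-column wrap)
#' @param seqs named character vector
#' @param path output file
#' @export
write_genome <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

slice_genome <- function(genome, chrom, start, end, strand = "+") {
  if (!chrom %in% names(genome)) stop("unknown chrom: ", chrom)
  s <- substring(genome[[chrom]], start + 1L, end)
  if (strand == "-") s <- revcomp(s) else s
}

parse_gff_attrs <- function(x) {
  parts <- strsplit(x, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  vals <- vapply(kv, function(p) if (length(p) >= 2) p[2] else "", "")
  names(vals) <- vapply(kv, `[`, "", 1)
  vals
}

read_gff3_lines <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  if (!any(keep)) {
    return(data.frame(chrom = character(0), type = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), attrs = character(0),
                      line = integer(0), stringsAsFactors = FALSE))
  }
  recs <- strsplit(lines[keep], "\t", fixed = TRUE)
  lineno <- which(keep)
  bad <- which(lengths(recs) != 9L)
  if (length(bad)) {
    stop("malformed GFF3 record at line ", lineno[bad[1]], " of ", path)
  }
  m <- do.call(rbind, recs)
  data.frame(chrom = m[, 1], type = m[, 3],
             start = as.integer(m[, 4]) - 1L,  # to 0-based half-open
             end = as.integer(m[, 5]), strand = m[, 7], attrs = m[, 9],
             line = lineno, stringsAsFactors = FALSE)
}

#' Read miRNA gene annotations from GFF3
#'
#' Expects `miRNA_primary_transcript` features with child `miRNA` (mature)
#' features. Coordinates are converted to the internal 0-based half-open
#' convention. When a genome is supplied, precursor sequences are extracted
#' (reverse-complemented on "-") and mature offsets are expressed 0-based
#' relative to the precursor 5' end.
#'
#' @param path GFF3 file
#' @param genome optional named character vector from [read_genome()]
#' @return data.frame with one row per miRNA gene: id, chrom, start, end,
#'   strand, family, mature_start, mature_end (genomic, 0-based half-open),
#'   n_mature, and, with a genome, precursor_seq, mature_offset, mature_len,
#'   mature_seq
#' @export
read_mirna_gff3 <- function(path, genome = NULL) {
  g <- read_gff3_lines(path)
  pri <- g[g$type == "miRNA_primary_transcript", , drop = FALSE]
  mat <- g[g$type == "miRNA", , drop = FALSE]
  if (nrow(pri) == 0) {
    return(data.frame(id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), family = character(0),
                      mature_start = integer(0), mature_end = integer(0),
                      n_mature = integer(0), stringsAsFactors = FALSE))
  }
  pa <- lapply(pri$attrs, parse_gff_attrs)
  ids <- vapply(pa, function(a) unname(a["ID"]), "")
  fam <- vapply(pa, function(a) {
    if ("Name" %in% names(a)) unname(a["Name"]) else unname(a["ID"])
  }, "")
  if (anyNA(ids) || any(!nzchar(ids))) {
    stop("miRNA_primary_transcript without ID in ", path)
  }
  ma <- lapply(mat$attrs, parse_gff_attrs)
  parent <- vapply(ma, function(a) unname(a["Parent"]), "")
  first_mat <- match(ids, parent)
  if (anyNA(first_mat)) {
    stop("miRNA gene without mature child feature: ",
         paste(ids[is.na(first_mat)], collapse = ", "))
  }
  out <- data.frame(id = ids, chrom = pri$chrom, start = pri$start,
                    end = pri$end, strand = pri$strand, family = fam,
                    mature_start = mat$start[first_mat],
                    mature_end = mat$end[first_mat],
                    n_mature = as.integer(table(factor(parent, levels = ids))),
                    stringsAsFactors = FALSE)
  if (!is.null(genome)) {
    out$precursor_seq <- mapply(slice_genome, out$chrom, out$start, out$end,
                                out$strand, MoreArgs = list(genome = genome))
    out$mature_len <- out$mature_end - out$mature_start
    out$mature_offset <- ifelse(out$strand == "+",
                                out$mature_start - out$start,
                                out$end - out$mature_end)
    bad <- out$mature_offset < 0 |
      out$mature_offset + out$mature_len > out$end - out$start
    if (any(bad)) stop("mature outside precursor for: ",
                       paste(out$id[bad], collapse = ", "))
    out$mature_seq <- substring(out$precursor_seq, out$mature_offset + 1L,
                                out$mature_offset + out$mature_len)
  }
  out
}

#' Write miRNA gene annotations to GFF3 (1-based closed)
#' @param mirnas data.frame as from [read_mirna_gff3()]
#' @param path output file
#' @export
write_mirna_gff3 <- function(mirnas, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(mirnas))) {
    r <- mirnas[i, ]
    writeLines(sprintf("%s\tmirorigin\tmiRNA_primary_transcript\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
                       r$chrom, r$start + 1L, r$end, r$strand, r$id, r$family), con)
    writeLines(sprintf("%s\tmirorigin\tmiRNA\t%d\t%d\t.\t%s\t.\tID=%s_mature;Parent=%s",
                       r$chrom, r$mature_start + 1L, r$mature_end, r$strand,
                       r$id, r$id), con)
  }
  invisible(path)
}

#' Read protein-coding gene models from GFF3
#'
#' Expects `gene` features with ID and an optional `isoforms` attribute
#' (count of annotated splice forms; the accompanying cDNA FASTA holds the
#' longest isoform only).
#'
#' @param path GFF3 file
#' @param cdna_path optional cDNA FASTA (ids must match gene IDs)
#' @param protein_path optional protein FASTA
#' @return data.frame: id, chrom, start, end, strand, isoform_count and
#'   optionally cdna_seq / protein_seq; rank = gene order along chromosome
#' @export
read_gene_gff3 <- function(path, cdna_path = NULL, protein_path = NULL) {
  g <- read_gff3_lines(path)
  g <- g[g$type == "gene", , drop = FALSE]
  pa <- lapply(g$attrs, parse_gff_attrs)
  ids <- vapply(pa, function(a) unname(a["ID"]), "")
  iso <- vapply(pa, function(a) {
    if ("isoforms" %in% names(a)) as.integer(a["isoforms"]) else 1L
  }, 1L)
  out <- data.frame(id = ids, chrom = g$chrom, start = g$start, end = g$end,
                    strand = g$strand, isoform_count = iso,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out$rank <- stats::ave(out$start, out$chrom, FUN = seq_along)
  rownames(out) <- NULL
  if (!is.null(cdna_path)) {
    cdna <- read_genome(cdna_path)
    out$cdna_seq <- unname(cdna[out$id])
  }
  if (!is.null(protein_path)) {
    prot <- Biostrings::readAAStringSet(protein_path)
    pv <- as.character(prot)
    names(pv) <- sub("\\s.*$", "", names(prot))
    out$protein_seq <- unname(pv[out$id])
  }
  out
}

#' Write gene models to GFF3
#' @param genes data.frame as from [read_gene_gff3()]
#' @param path output file
#' @export
write_gene_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(genes))) {
    r <- genes[i, ]
    writeLines(sprintf("%s\tmirorigin\tgene\t%d\t%d\t.\t%s\t.\tID=%s;isoforms=%d",
                       r$chrom, r$start + 1L, r$end, r$strand, r$id,
                       r$isoform_count), con)
  }
  invisible(path)
}

#' Classify a repeat family/class string as MITE
#'
#' Stowaway and Tourist families, and anything explicitly flagged "MITE",
#' count as miniature inverted-repeat transposable elements.
#' @param repeat_class character vector of class/family strings
#' @return logical vector
#' @export
is_mite_class <- function(repeat_class) {
  grepl("Stowaway|Tourist|MITE", repeat_class, ignore.case = TRUE)
}

#' Read a RepeatMasker-out-style repeat table
#'
#' Tab-separated with header: score, divergence, chrom, begin, end, strand,
#' repeat_name, repeat_class. File coordinates are 1-based closed (as in
#' RepeatMasker .out); internal are 0-based half-open.
#' @param path TSV file
#' @return data.frame with is_mite flag added
#' @export
read_repeat_table <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, quote = "")
  need <- c("score", "divergence", "chrom", "begin", "end", "strand",
            "repeat_name", "repeat_class")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("repeat table missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(x$divergence < 0)) stop("negative divergence in repeat table")
  data.frame(chrom = x$chrom, start = x$begin - 1L, end = x$end,
             strand = x$strand, family = x$repeat_name,
             repeat_class = x$repeat_class, divergence = x$divergence,
             score = x$score, is_mite = is_mite_class(x$repeat_class),
             stringsAsFactors = FALSE)
}

#' Write a repeat table (RepeatMasker-out-like TSV)
#' @param repeats internal repeat data.frame
#' @param path output file
#' @export
write_repeat_table <- function(repeats, path) {
  out <- data.frame(score = repeats$score, divergence = repeats$divergence,
                    chrom = repeats$chrom, begin = repeats$start + 1L,
                    end = repeats$end, strand = repeats$strand,
                    repeat_name = repeats$family,
                    repeat_class = repeats$repeat_class)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pseudogene table
#'
#' TSV with header id, chrom, start, end, strand, parent_gene_id; file
#' coordinates 1-based closed. Unknown parents are recorded as NA.
#' @param path TSV file
#' @return data.frame (internal coordinates)
#' @export
read_pseudogene_table <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, quote = "")
  data.frame(id = x$id, chrom = x$chrom, start = x$start - 1L, end = x$end,
             strand = x$strand,
             parent_gene = ifelse(x$parent_gene_id %in% c("", "."), NA,
                                  x$parent_gene_id),
             stringsAsFactors = FALSE)
}

#' Write a pseudogene table
#' @param pseudogenes internal pseudogene data.frame
#' @param path output file
#' @export
write_pseudogene_table <- function(pseudogenes, path) {
  out <- data.frame(id = pseudogenes$id, chrom = pseudogenes$chrom,
                    start = pseudogenes$start + 1L, end = pseudogenes$end,
                    strand = pseudogenes$strand,
                    parent_gene_id = ifelse(is.na(pseudogenes$parent_gene),
                                            ".", pseudogenes$parent_gene))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED6 track (already 0-based half-open)
#' @param path BED file
#' @return data.frame chrom, start, end, name, score, strand
#' @export
read_bed <- function(path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  if (file.size(path) == 0) {
    x <- data.frame(chrom = character(0), start = integer(0),
                    end = integer(0), name = character(0),
                    score = integer(0), strand = character(0))
    return(x)
  }
  utils::read.table(path, header = FALSE, sep = "\t",
                    stringsAsFactors = FALSE, quote = "", col.names = cols)
}

#' Write a BED6 track
#' @param track data.frame with chrom, start, end, name, score, strand
#' @param path output file
#' @export
write_bed <- function(track, path) {
  utils::write.table(track[, c("chrom", "start", "end", "name", "score",
                               "strand")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Load a full annotation bundle directory
#'
#' Reads the files emitted by [generate_genome()] (or equivalently prepared
#' user data) into one list used by the downstream stages. Optional tracks
#' that are absent become NULL.
#' @param dir bundle directory
#' @return list with genome, mirnas, repeats, pseudogenes, genes, tracks,
#'   expression, species (catalog list), truth
#' @export
read_bundle <- function(dir) {
  p <- function(...) file.path(dir, ...)
  genome <- read_genome(p("genome.fa"))
  b <- list(
    dir = dir,
    genome = genome,
    mirnas = read_mirna_gff3(p("mirna.gff3"), genome),
    repeats = read_repeat_table(p("repeats.tsv")),
    pseudogenes = read_pseudogene_table(p("pseudogenes.tsv")),
    genes = read_gene_gff3(p("genes.gff3"), p("cdna.fa"), p("protein.fa"))
  )
  b$tracks <- list()
  for (tr in c("sirna", "promoters", "methylation", "polymorphic")) {
    f <- p("tracks", paste0(tr, ".bed"))
    b$tracks[[tr]] <- if (file.exists(f)) read_bed(f) else NULL
  }
  f <- p("expression.tsv")
  b$expression <- if (file.exists(f)) {
    utils::read.table(f, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  } else NULL
  spdir <- p("species")
  b$species <- if (dir.exists(spdir)) {
    fa <- list.files(spdir, pattern = "\\.fa$", full.names = TRUE)
    stats::setNames(lapply(fa, read_genome),
                    sub("\\.fa$", "", basename(fa)))
  } else NULL
  f <- p("truth.tsv")
  b$truth <- if (file.exists(f)) {
    utils::read.table(f, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  } else NULL
  b
}
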
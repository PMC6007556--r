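#' Read FASTA / FASTQ files into tibbles
#'
#' Thin wrappers over [Biostrings::readDNAStringSet()]: multi-record,
#' wrapped or unwrapped lines, CRLF endings and gzip compression are all
#' handled transparently. Record ids are truncated at the first whitespace.
#'
#' @param path file path (optionally gzipped).
#' @return `read_fasta`: tibble with `id`, `sequence`; `read_fastq` adds
#'   `quality`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readDNAStringSet(path, format = "fasta")
  tibble(id = sub("\\s.*$", "", names(ss)),
         sequence = unname(as.character(ss)))
}

#' @rdname read_fasta
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  tibble(
    id = sub("\\s.*$", "", names(ss)),
    sequence = unname(as.character(ss)),
    quality = unname(as.character(S4Vectors::mcols(ss)$qualities))
  )
}

#' Write sequences to FASTA / FASTQ
#'
#' @param x tibble with `id` and `sequence` (and `quality` for FASTQ;
#'   a constant `"I"` quality is filled in when absent).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  ss <- Biostrings::DNAStringSet(setNames(x$sequence, x$id))
  Biostrings::writeXStringSet(ss, path, format = "fasta")
  invisible(path)
}

#' @rdname write_fasta
#' @export
write_fastq <- function(x, path) {
  qual <- if ("quality" %in% names(x)) x$quality else strrep("I", nchar(x$sequence))
  ss <- Biostrings::DNAStringSet(setNames(x$sequence, x$id))
  Biostrings::writeXStringSet(ss, path, format = "fastq",
                              qualities = Biostrings::BStringSet(qual))
  invisible(path)
}

#' Write pair placements as SAM
#'
#' Emits two records per placed pair (one per read) against the index's
#' contig table. Positions are converted to 1-based here and nowhere else.
#' Conventions: MAPQ 60 for score-reported reads and 30 for rescued mates;
#' CIGAR is a full-length `M` placeholder (no base-level alignment is
#' computed); unplaced pairs are omitted; rescued mates carry `XR:i:1`.
#' FLAG bits used: 0x1 paired, 0x2 both mates on one contig, 0x10/0x20
#' read/mate reverse strand, 0x40/0x80 first/second of pair. TLEN is the
#' signed outer distance, positive on the leftmost mate, zero across
#' contigs.
#'
#' @param placements placement tibble from [map_read_pairs()] (sequence
#'   columns `qf`/`qr` are used for SEQ when present).
#' @param index the `kmer_index` the placements were produced with (or its
#'   `contigs` tibble).
#' @param path output path.
#' @param program_id string recorded in the `@PG` header line.
#' @return `path`, invisibly.
#' @export
write_sam <- function(placements, index, path, program_id = "kmerlink") {
  contigs <- if (inherits(index, "kmer_index")) index$contigs else index
  if (anyDuplicated(contigs$contig)) stop("contig name collision in contig table")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", contigs$contig, contigs$length),
    sprintf("@PG\tID:%s\tPN:%s", program_id, program_id)
  ), con)
  if (is.null(placements) || nrow(placements) == 0) return(invisible(path))

  p <- placements[placements$placed, , drop = FALSE]
  if (nrow(p) == 0) return(invisible(path))
  seq_f <- if ("qf" %in% names(p)) p$qf else strrep("N", p$f_read_len)
  seq_r <- if ("qr" %in% names(p)) p$qr else strrep("N", p$r_read_len)
  qname <- if ("id" %in% names(p)) p$id else sprintf("pair_%d", seq_len(nrow(p)))

  same <- p$f_contig_id == p$r_contig_id
  base_flag <- 1L + ifelse(same, 2L, 0L)
  f_flag <- base_flag + 64L + ifelse(p$f_strand == "-", 16L, 0L) +
    ifelse(p$r_strand == "-", 32L, 0L)
  r_flag <- base_flag + 128L + ifelse(p$r_strand == "-", 16L, 0L) +
    ifelse(p$f_strand == "-", 32L, 0L)
  f_pos <- p$f_start + 1L
  r_pos <- p$r_start + 1L
  tlen_f <- ifelse(!same, 0L, ifelse(f_pos <= r_pos, p$observed_insert,
                                     -p$observed_insert))
  # rescued flag applies to the mate that was rescued (the lower scorer)
  f_rescued <- p$rescued & p$f_score <= p$r_score
  r_rescued <- p$rescued & !f_rescued
  fmt <- function(flag, rname, pos, mapq, cigar_len, rnext, pnext, tlen,
                  sq, rescued) {
    paste0(qname, "\t", flag, "\t", rname, "\t", pos, "\t", mapq, "\t",
           cigar_len, "M\t", rnext, "\t", pnext, "\t", tlen, "\t", sq,
           "\t", strrep("I", nchar(sq)),
           ifelse(rescued, "\tXR:i:1", ""))
  }
  f_lines <- fmt(f_flag, contigs$contig[p$f_contig_id], f_pos,
                 ifelse(f_rescued, 30L, 60L), nchar(seq_f),
                 ifelse(same, "=", contigs$contig[p$r_contig_id]), r_pos,
                 tlen_f, seq_f, f_rescued)
  r_lines <- fmt(r_flag, contigs$contig[p$r_contig_id], r_pos,
                 ifelse(r_rescued, 30L, 60L), nchar(seq_r),
                 ifelse(same, "=", contigs$contig[p$f_contig_id]), f_pos,
                 -tlen_f, seq_r, r_rescued)
  out <- character(2L * nrow(p))
  out[seq(1, length(out), by = 2)] <- f_lines
  out[seq(2, length(out), by = 2)] <- r_lines
  writeLines(out, con)
  invisible(path)
}

#' Read a SAM file of pair placements back into a placement tibble
#'
#' Inverse of [write_sam()] for the subset of SAM this package emits: paired
#' records in first/second order, placeholder CIGARs, `XR:i:1` rescue tags.
#' Intended for feeding previously written alignments into
#' [build_scaffold_graph()].
#'
#' @param path SAM file path.
#' @return list with `contigs` (tibble `contig_id`, `contig`, `length`) and
#'   `placements` (tibble in the [map_read_pairs()] layout).
#' @export
read_sam_placements <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  sq <- hdr[startsWith(hdr, "@SQ")]
  contigs <- tibble(
    contig_id = seq_along(sq),
    contig = sub("^.*\tSN:([^\t]+).*$", "\\1", sq),
    length = as.integer(sub("^.*\tLN:([0-9]+).*$", "\\1", sq))
  )
  rec <- lines[!startsWith(lines, "@")]
  if (length(rec) == 0) {
    return(list(contigs = contigs, placements = .empty_placements()))
  }
  fld <- strsplit(rec, "\t")
  g <- function(i) vapply(fld, `[[`, "", i)
  flag <- as.integer(g(2))
  d <- tibble(
    id = g(1), flag = flag, rname = g(3), pos = as.integer(g(4)),
    seq = g(10),
    first = bitwAnd(flag, 64L) > 0L,
    reverse = bitwAnd(flag, 16L) > 0L,
    rescued = vapply(fld, function(f) any(f == "XR:i:1"), logical(1))
  )
  f <- d[d$first, ]
  r <- d[!d$first, ]
  r <- r[match(f$id, r$id), ]
  fc <- match(f$rname, contigs$contig)
  rc <- match(r$rname, contigs$contig)
  same <- fc == rc
  fs <- f$pos - 1L
  rs <- r$pos - 1L
  fe <- fs + nchar(f$seq)
  re <- rs + nchar(r$seq)
  tibble(
    id = f$id, placed = TRUE,
    f_contig_id = fc, f_start = fs, f_strand = ifelse(f$reverse, "-", "+"),
    f_score = NA_integer_, f_read_len = nchar(f$seq),
    r_contig_id = rc, r_start = rs, r_strand = ifelse(r$reverse, "-", "+"),
    r_score = NA_integer_, r_read_len = nchar(r$seq),
    rescued = f$rescued | r$rescued,
    observed_insert = ifelse(same, pmax(fe, re) - pmin(fs, rs), NA_integer_),
    orientation = ifelse(same,
                         .pair_orientation(fs, ifelse(f$reverse, "-", "+"), nchar(f$seq),
                                           rs, ifelse(r$reverse, "-", "+"), nchar(r$seq)),
                         NA_character_),
    qf = f$seq, qr = r$seq
  ) -> out
  list(contigs = contigs, placements = out)
}
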
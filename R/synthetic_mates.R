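#' Parameters for synthetic mate-pair extraction from long reads
#'
#' Synthetic pairs are 200 bp windows cut from a long read in
#' forward-reverse orientation at a nominal outer distance D, sliding by
#' 100 bp; mapping uses the long-read defaults (hit capacity 20, minimum
#' score 15, minimum rescue score 4). `insert_sizes` takes the role of D
#' and may list several values to extract linking information at multiple
#' scales.
#'
#' @param insert_sizes integer vector of nominal outer distances D; each
#'   must be at least `2 * read_length`.
#' @param read_length bases per synthetic read.
#' @param step sliding offset between consecutive extractions.
#' @param min_score report threshold passed to the mapper (strictly
#'   greater than).
#' @param min_rescue_score rescue threshold.
#' @param hit_capacity hits collected per read.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(insert_sizes, read_length = 200L, step = 100L,
                           min_score = 15L, min_rescue_score = 4L,
                           hit_capacity = 20L) {
  insert_sizes <- as.integer(insert_sizes)
  stopifnot(length(insert_sizes) >= 1, step >= 1, read_length >= 1,
            all(insert_sizes >= 2L * read_length))
  structure(list(insert_sizes = insert_sizes,
                 read_length = as.integer(read_length),
                 step = as.integer(step),
                 min_score = as.integer(min_score),
                 min_rescue_score = as.integer(min_rescue_score),
                 hit_capacity = as.integer(hit_capacity)),
            class = "synthetic_spec")
}

#' Cut synthetic mate-pairs out of long reads
#'
#' For every insert size D and every start s in `{0, step, 2*step, ...}`
#' with `s + D <= read length`, emits the pair `qf = read[s, s+rl)` and
#' `qr = revcomp(read[s+D-rl, s+D))`, where `rl` is the read length of the
#' spec. D is the outer distance (first base of qf to last base of qr,
#' inclusive), so an error-free pair maps with observed insert exactly D,
#' and reverse-complementing qr at extraction makes every emitted pair
#' physically forward-reverse. Pair ids are `<read_id>:<s>:<D>` so
#' provenance is recoverable from SAM output.
#'
#' @param long_reads tibble with `id` and `sequence` columns (e.g. from
#'   [read_fastq()]), or a character vector of sequences.
#' @param spec a [synthetic_spec()].
#' @return tibble with `id`, `qf`, `qr`, `library_tag` (D),
#'   `source_read_id`, `source_offset` (s). Reads shorter than a given D
#'   contribute no pairs for that D.
#' @export
extract_synthetic_pairs <- function(long_reads, spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.character(long_reads)) {
    long_reads <- tibble(
      id = if (is.null(names(long_reads)))
        sprintf("read_%d", seq_along(long_reads)) else names(long_reads),
      sequence = unname(long_reads))
  }
  rl <- spec$read_length
  out <- vector("list", nrow(long_reads) * length(spec$insert_sizes))
  j <- 0L
  for (i in seq_len(nrow(long_reads))) {
    sq <- long_reads$sequence[[i]]
    L <- nchar(sq)
    for (D in spec$insert_sizes) {
      if (L < D) next
      s <- seq.int(0L, L - D, by = spec$step)
      qf <- substring(sq, s + 1L, s + rl)
      qr <- revcomp(substring(sq, s + D - rl + 1L, s + D))
      j <- j + 1L
      out[[j]] <- tibble(
        id = sprintf("%s:%d:%d", long_reads$id[[i]], s, D),
        qf = qf, qr = qr, library_tag = D,
        source_read_id = long_reads$id[[i]], source_offset = as.integer(s))
    }
  }
  if (j == 0L) {
    return(tibble(id = character(), qf = character(), qr = character(),
                  library_tag = integer(), source_read_id = character(),
                  source_offset = integer()))
  }
  dplyr::bind_rows(out[seq_len(j)])
}

#' Extract and map synthetic mate-pairs from long reads
#'
#' Cuts synthetic pairs per [extract_synthetic_pairs()] and places each
#' with the alignment-free pair mapper under the long-read defaults of the
#' spec. Placements carry their `library_tag` so per-library SAM files and
#' per-library parameter estimates can be produced downstream; the
#' per-library outputs partition the emitted pairs.
#'
#' @param long_reads tibble with `id`, `sequence` (or character vector).
#' @param index a `kmer_index` built with a long-read-appropriate k
#'   (15-22 is the sensible range at 10-15\% read error).
#' @param spec a [synthetic_spec()].
#' @param libs optional named list of [library_params()] keyed by insert
#'   size (as character), enabling pair rescue per library; `NULL` maps
#'   without rescue.
#' @return placement tibble (see [map_read_pairs()]) with `library_tag`,
#'   `source_read_id` and `source_offset` columns.
#' @export
map_long_read_pairs <- function(long_reads, index, spec, libs = NULL) {
  pairs <- extract_synthetic_pairs(long_reads, spec)
  out <- vector("list", length(spec$insert_sizes))
  for (i in seq_along(spec$insert_sizes)) {
    D <- spec$insert_sizes[i]
    sub <- pairs[pairs$library_tag == D, , drop = FALSE]
    if (nrow(sub) == 0) next
    lib <- if (!is.null(libs)) libs[[as.character(D)]] else NULL
    params <- mapper_params(hit_capacity = spec$hit_capacity,
                            min_report_score = spec$min_score,
                            min_rescue_score = spec$min_rescue_score,
                            lib = lib)
    pl <- map_read_pairs(sub[, c("id", "qf", "qr")], index, params)
    pl$library_tag <- D
    pl$source_read_id <- sub$source_read_id
    pl$source_offset <- sub$source_offset
    out[[i]] <- pl
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) {
    e <- .empty_placements()
    e$library_tag <- integer()
    e$source_read_id <- character()
    e$source_offset <- integer()
    return(e)
  }
  dplyr::bind_rows(out)
}
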
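#' Mapping parameters for alignment-free pair placement
#'
#' Defaults follow the method's printed short-read settings: up to 10 hits
#' collected per read, a strict forward gate of score > 3 before the mate is
#' even examined, reporting when both reads score strictly above 5, and a
#' rescued mate accepted at score >= 4. Long-read (synthetic mate-pair)
#' mapping uses capacity 20 and a report threshold of 15 (see
#' [synthetic_spec()]).
#'
#' @param hit_capacity maximum hits stored per read.
#' @param min_fwd_score forward-read gate; the mate is only examined when
#'   the forward score is strictly greater than this.
#' @param min_report_score per-read report threshold (strictly greater
#'   than).
#' @param min_rescue_score minimum score (at least) for a rescued mate.
#' @param lib a [library_params()] object, or `NULL` to disable pair
#'   rescue.
#' @return a list of class `mapper_params`.
#' @export
mapper_params <- function(hit_capacity = 10L, min_fwd_score = 3L,
                          min_report_score = 5L, min_rescue_score = 4L,
                          lib = NULL) {
  stopifnot(hit_capacity >= 1, min_fwd_score >= 0, min_report_score >= 0,
            min_rescue_score >= 0)
  structure(list(hit_capacity = as.integer(hit_capacity),
                 min_fwd_score = as.integer(min_fwd_score),
                 min_report_score = as.integer(min_report_score),
                 min_rescue_score = as.integer(min_rescue_score),
                 lib = lib),
            class = "mapper_params")
}

#' Collect unique k-mer hits for one read
#'
#' Scans the read's k-mers left to right, querying each (canonically, so
#' both strands are covered) against the index, and stops once `capacity`
#' hits are stored or the read is exhausted. Hits are whatever survives the
#' fingerprint check, so the occasional false positive enters the hit
#' vector exactly as it would in the emulated dictionary; window scoring is
#' what filters such strays out.
#'
#' @param read a single read sequence.
#' @param index a `kmer_index`.
#' @param capacity maximum number of hits to store.
#' @return tibble with `contig_id`, `coordinate` (0-based k-mer start on
#'   the contig), `strand` (`"+"` when the read k-mer matches the contig
#'   forward strand) and `read_offset` (0-based k-mer start in the read).
#' @export
collect_hits <- function(read, index, capacity = 10L) {
  stopifnot(inherits(index, "kmer_index"))
  h <- .cpp_collect_hits(index$ptr, read, as.integer(capacity))
  out <- tibble(contig_id = h$contig_id, coordinate = h$coordinate,
                strand = ifelse(h$forward, "+", "-"),
                read_offset = h$read_offset)
  attr(out, "k") <- index$k
  out
}

#' Window-score a hit collection
#'
#' Hits are grouped by contig and match strand, each hit is projected to an
#' inferred read start (strand-adjusted), and the score is the maximum
#' number of hits falling inside any window whose width equals the read
#' length. If two maximal windows sit at distinct genomic locations the
#' read is flagged ambiguous and treated as score 0 for reporting;
#' overlapping maximal windows at one location are not ambiguity.
#'
#' @param hits tibble from [collect_hits()] (columns `contig_id`,
#'   `coordinate`, `strand`, `read_offset`).
#' @param read_length read length in bases (window width).
#' @param k k-mer length used to collect the hits; defaults to the
#'   attribute set by [collect_hits()].
#' @return one-row tibble: `score`, `effective_score` (0 when ambiguous),
#'   `ambiguous`, `contig_id`, `strand`, `start` (0-based inferred read
#'   start of the representative hit, unclamped), `rep_offset`.
#' @export
score_read <- function(hits, read_length, k = attr(hits, "k")) {
  if (is.null(k)) stop("supply `k` (hits lack a k attribute)")
  s <- .cpp_score_read(as.integer(hits$contig_id), hits$strand == "+",
                       as.integer(hits$coordinate),
                       as.integer(hits$read_offset),
                       as.integer(k), as.integer(read_length))
  tibble(score = s$score,
         effective_score = if (s$ambiguous) 0L else s$score,
         ambiguous = s$ambiguous, contig_id = s$contig_id,
         strand = s$strand, start = s$start, rep_offset = s$rep_offset)
}

# orientation of a same-contig pair: direction of the leftmost read, then
# the rightmost (FR = innie). Ties on start use the first read as leftmost.
.pair_orientation <- function(s1, d1, l1, s2, d2, l2) {
  left_first <- s1 <= s2
  lo <- ifelse(left_first, d1, d2)
  hi <- ifelse(left_first, d2, d1)
  paste0(ifelse(lo == "+", "F", "R"), ifelse(hi == "+", "F", "R"))
}

.empty_placements <- function() {
  tibble(id = character(), placed = logical(),
         f_contig_id = integer(), f_start = integer(), f_strand = character(),
         f_score = integer(), f_read_len = integer(),
         r_contig_id = integer(), r_start = integer(), r_strand = character(),
         r_score = integer(), r_read_len = integer(),
         rescued = logical(), observed_insert = integer(),
         orientation = character(), qf = character(), qr = character())
}

# core per-pair algorithm; returns NULL or a plain list
.map_pair_core <- function(qf, qr, index, params) {
  k <- index$k
  lf <- nchar(qf)
  lr <- nchar(qr)
  hf <- .cpp_collect_hits(index$ptr, qf, params$hit_capacity)
  sf <- .cpp_score_read(hf$contig_id, hf$forward, hf$coordinate,
                        hf$read_offset, k, lf)
  ef <- if (sf$ambiguous) 0L else sf$score
  if (!(ef > params$min_fwd_score)) return(NULL)
  hr <- .cpp_collect_hits(index$ptr, qr, params$hit_capacity)
  sr <- .cpp_score_read(hr$contig_id, hr$forward, hr$coordinate,
                        hr$read_offset, k, lr)
  er <- if (sr$ambiguous) 0L else sr$score
  rescued <- FALSE
  if (ef > params$min_report_score && er > params$min_report_score) {
    # report as scored
  } else if (!is.null(params$lib)) {
    if (ef >= er) {
      if (!(ef > params$min_report_score)) return(NULL)
      rs <- .rescue_core(sf, lf, hr, lr, index, params)
      if (is.null(rs)) return(NULL)
      sr <- rs
      er <- rs$score
    } else {
      if (!(er > params$min_report_score)) return(NULL)
      rs <- .rescue_core(sr, lr, hf, lf, index, params)
      if (is.null(rs)) return(NULL)
      sf <- rs
      ef <- rs$score
    }
    rescued <- TRUE
  } else {
    return(NULL)
  }
  clamp <- function(s, contig_id, len) {
    max(0L, min(s, index$contigs$length[contig_id] - len))
  }
  f_start <- clamp(sf$start, sf$contig_id, lf)
  r_start <- clamp(sr$start, sr$contig_id, lr)
  same <- sf$contig_id == sr$contig_id
  list(f_contig_id = sf$contig_id, f_start = f_start, f_strand = sf$strand,
       f_score = ef, f_read_len = lf,
       r_contig_id = sr$contig_id, r_start = r_start, r_strand = sr$strand,
       r_score = er, r_read_len = lr,
       rescued = rescued,
       observed_insert = if (same)
         max(f_start + lf, r_start + lr) - min(f_start, r_start) else NA_integer_,
       orientation = if (same)
         .pair_orientation(f_start, sf$strand, lf, r_start, sr$strand, lr)
       else NA_character_)
}

# rescue: keep mate hits whose implied placement satisfies the library's
# expected distance (mu +/- 3 sd) and orientation, then window-score them
.rescue_core <- function(fixed, fixed_len, mate_hits, mate_len, index, params) {
  lib <- params$lib
  if (is.null(lib) || length(mate_hits$contig_id) == 0) return(NULL)
  k <- index$k
  keep <- logical(length(mate_hits$contig_id))
  lo <- lib$mean_insert - 3 * lib$sd_insert
  hi <- lib$mean_insert + 3 * lib$sd_insert
  for (i in seq_along(keep)) {
    if (mate_hits$contig_id[i] != fixed$contig_id) next
    ms <- if (mate_hits$forward[i]) {
      mate_hits$coordinate[i] - mate_hits$read_offset[i]
    } else {
      mate_hits$coordinate[i] + mate_hits$read_offset[i] + k - mate_len
    }
    ins <- max(fixed$start + fixed_len, ms + mate_len) - min(fixed$start, ms)
    if (ins < lo || ins > hi) next
    orient <- .pair_orientation(fixed$start, fixed$strand, fixed_len,
                                ms, if (mate_hits$forward[i]) "+" else "-",
                                mate_len)
    if (orient != lib$orientation) next
    keep[i] <- TRUE
  }
  if (!any(keep)) return(NULL)
  s <- .cpp_score_read(mate_hits$contig_id[keep],
                       mate_hits$forward[keep],
                       mate_hits$coordinate[keep],
                       mate_hits$read_offset[keep], k, mate_len)
  if (s$ambiguous || s$score < params$min_rescue_score) return(NULL)
  s
}

#' Place one read pair
#'
#' Implements the gated pair-placement algorithm: forward hits are
#' collected and scored; unless the forward score is strictly greater than
#' `min_fwd_score` the pair is abandoned. Otherwise the reverse read is
#' scored; if both reads score strictly above `min_report_score`
#' (unambiguously) the pair is reported, and otherwise a pair rescue is
#' attempted by fixing the better-scored read and re-scoring the mate's
#' hits under the library's distance and orientation constraints.
#'
#' @param qf,qr forward and reverse read sequences.
#' @param index a `kmer_index`.
#' @param params a [mapper_params()].
#' @return a one-row placement tibble, or `NULL` when the pair is not
#'   placeable.
#' @export
map_pair <- function(qf, qr, index, params = mapper_params()) {
  stopifnot(nchar(qf) > 0, nchar(qr) > 0)
  res <- .map_pair_core(qf, qr, index, params)
  if (is.null(res)) return(NULL)
  out <- as_tibble(c(list(id = "pair_1", placed = TRUE), res))
  out$qf <- qf
  out$qr <- qr
  out
}

#' Rescue a poorly scoring mate against a fixed placement
#'
#' @param fixed one-row tibble from [score_read()] for the well-placed
#'   read (`contig_id`, `start`, `strand` are used).
#' @param fixed_length length of the fixed read in bases.
#' @param mate the mate's read sequence.
#' @param index a `kmer_index`.
#' @param params a [mapper_params()] whose `lib` supplies the expected
#'   insert mean/sd and orientation; without a library the rescue is
#'   silently skipped (`NULL`).
#' @return one-row tibble like [score_read()]'s, or `NULL` when no
#'   conforming placement reaches `min_rescue_score`.
#' @export
rescue_pair <- function(fixed, fixed_length, mate, index,
                        params = mapper_params()) {
  if (is.null(params$lib)) return(NULL)
  hits <- .cpp_collect_hits(index$ptr, mate, params$hit_capacity)
  s <- .rescue_core(as.list(fixed[1, ]), fixed_length, hits, nchar(mate),
                    index, params)
  if (is.null(s)) return(NULL)
  tibble(score = s$score, effective_score = s$score, ambiguous = s$ambiguous,
         contig_id = s$contig_id, strand = s$strand, start = s$start,
         rep_offset = s$rep_offset)
}

#' Place a table of read pairs
#'
#' Data-frame-first mapper: takes a tibble of pairs and returns one row per
#' pair with placement status, so results pipe straight into
#' [estimate_library_illumina()], [build_scaffold_graph()] or
#' [write_sam()]. Run statistics (pairs read / placed / rescued /
#' cross-contig linking fraction) are attached as the `"stats"` attribute
#' and available via [mapping_stats()].
#'
#' @param pairs tibble with columns `qf` and `qr` (and optionally `id`).
#' @param index a `kmer_index`.
#' @param params a [mapper_params()].
#' @param keep_sequences keep `qf`/`qr` columns on the output (needed for
#'   SAM emission).
#' @return placement tibble; unplaceable pairs appear with `placed = FALSE`.
#' @export
map_read_pairs <- function(pairs, index, params = mapper_params(),
                           keep_sequences = TRUE) {
  stopifnot(is.data.frame(pairs), all(c("qf", "qr") %in% names(pairs)))
  n <- nrow(pairs)
  ids <- if ("id" %in% names(pairs)) as.character(pairs$id) else
    sprintf("pair_%d", seq_len(n))
  res <- vector("list", n)
  for (i in seq_len(n)) {
    # res[i] <- list(...): assigning a bare NULL into [[ ]] would drop the slot
    res[i] <- list(.map_pair_core(pairs$qf[[i]], pairs$qr[[i]], index, params))
  }
  placed <- !vapply(res, is.null, logical(1))
  tpl <- list(f_contig_id = NA_integer_, f_start = NA_integer_,
              f_strand = NA_character_, f_score = NA_integer_,
              f_read_len = NA_integer_, r_contig_id = NA_integer_,
              r_start = NA_integer_, r_strand = NA_character_,
              r_score = NA_integer_, r_read_len = NA_integer_,
              rescued = FALSE, observed_insert = NA_integer_,
              orientation = NA_character_)
  rows <- lapply(seq_len(n), function(i) {
    r <- if (placed[i]) res[[i]] else tpl
    r$observed_insert <- as.integer(r$observed_insert)
    r
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::bind_cols(tibble(id = ids, placed = placed), out)
  if (keep_sequences) {
    out$qf <- pairs$qf
    out$qr <- pairs$qr
  }
  same <- out$placed & out$f_contig_id == out$r_contig_id
  attr(out, "stats") <- tibble(
    pairs_read = n,
    pairs_placed = sum(placed),
    pairs_rescued = sum(out$rescued, na.rm = TRUE),
    pairs_linking = sum(out$placed & !same),
    linking_fraction = if (sum(placed) > 0)
      sum(out$placed & !same) / sum(placed) else NA_real_
  )
  out
}

#' Run statistics attached to a placement tibble
#'
#' @param placements result of [map_read_pairs()].
#' @return one-row tibble of counts (pairs read, placed, rescued, linking)
#'   and the linking fraction.
#' @export
mapping_stats <- function(placements) {
  s <- attr(placements, "stats")
  if (is.null(s)) stop("no run statistics attached; was this produced by map_read_pairs()?")
  s
}
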
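#' Build a unique k-mer index over a set of contigs
#'
#' Indexes every canonical k-mer that occurs exactly once (counting both
#' strands) across the contig set, storing for each its contig of origin,
#' 0-based coordinate and strand. Membership queries are verified with a
#' 16-bit fingerprint, so a query for an absent k-mer succeeds spuriously
#' with probability about \eqn{2^{-16} = 0.0000152}, mirroring the behaviour
#' of a minimal-perfect-hash dictionary with fingerprint control. Stored
#' k-mers are always found (no false negatives).
#'
#' Construction is deterministic and independent of how the contigs are
#' chunked: counting aggregates over chunks of `chunk_size` starting
#' positions and the final slot order is sorted by key hash.
#'
#' @param contigs named character vector of contig sequences, a
#'   [Biostrings::DNAStringSet], a tibble with columns `contig` and
#'   `sequence`, or the path to a FASTA file.
#' @param k k-mer length, between 15 and 256.
#' @param chunk_size number of k-mer start positions per construction chunk;
#'   affects nothing but internal batching (default 5e6, matching 5 Mb
#'   chunks of contig sequence).
#' @return an object of class `kmer_index` with elements `k`,
#'   `fingerprint_bits`, `n_keys` and `contigs` (a tibble with `contig_id`,
#'   `contig`, `length`).
#' @examples
#' idx <- kmer_index(c(c1 = "ACGTACGTTGCACCGTAGGCTTAAG"), k = 15)
#' idx$n_keys
#' @export
kmer_index <- function(contigs, k = 21, chunk_size = 5e6) {
  contigs <- .as_contig_set(contigs)
  ptr <- .cpp_build_index(names(contigs), unname(contigs), as.integer(k),
                          as.double(chunk_size))
  .wrap_index(ptr)
}

.as_contig_set <- function(contigs) {
  if (is.data.frame(contigs)) {
    stopifnot(all(c("contig", "sequence") %in% names(contigs)))
    return(setNames(as.character(contigs$sequence), contigs$contig))
  }
  if (inherits(contigs, "DNAStringSet")) {
    return(setNames(as.character(contigs), names(contigs)))
  }
  if (is.character(contigs) && length(contigs) == 1L && !grepl("[ACGTNacgtn]{20}", contigs) &&
      file.exists(contigs)) {
    fa <- read_fasta(contigs)
    return(setNames(fa$sequence, fa$id))
  }
  if (is.character(contigs)) {
    if (is.null(names(contigs))) {
      names(contigs) <- sprintf("contig_%03d", seq_along(contigs))
    }
    return(contigs)
  }
  stop("cannot interpret `contigs`; supply sequences or a FASTA path")
}

.wrap_index <- function(ptr) {
  info <- .cpp_index_info(ptr)
  structure(
    list(
      ptr = ptr,
      k = info$k,
      fingerprint_bits = info$fingerprint_bits,
      n_keys = info$n_keys,
      contigs = tibble(
        contig_id = seq_along(info$contig),
        contig = info$contig,
        length = info$length
      )
    ),
    class = "kmer_index"
  )
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf(
    "<kmer_index> k=%d  keys=%s  fingerprint=%d bits  contigs=%d (%s bp)\n",
    x$k, format(x$n_keys, big.mark = ","), x$fingerprint_bits,
    nrow(x$contigs), format(sum(as.numeric(x$contigs$length)), big.mark = ",",
                            scientific = FALSE)
  ))
  invisible(x)
}

#' Stream of canonical k-mer hashes along a sequence
#'
#' Computes a strand-canonical 64-bit hash for every k-mer of `sequence`
#' consisting only of A/C/G/T; positions whose window contains any other
#' symbol are skipped. The hash of a k-mer equals the hash of its reverse
#' complement. Work per consecutive offset is amortised constant for
#' k up to 32 (2-bit rolling encoding).
#'
#' @param sequence a single nucleotide string.
#' @param k k-mer length.
#' @return tibble with `offset` (0-based), `hash` (16-hex-digit string) and
#'   `forward_canonical` (whether the forward form is the canonical one,
#'   i.e. the lexicographic minimum of the k-mer and its reverse complement).
#' @export
canonical_hashes <- function(sequence, k) {
  stopifnot(is.character(sequence), length(sequence) == 1L, k >= 1)
  as_tibble(.cpp_hash_stream(sequence, as.integer(k)))
}

#' Count canonical k-mers across contigs
#'
#' Aggregates occurrences of each k-mer and its reverse complement under
#' the canonical (lexicographic-minimum) form. Used for unique-k-mer
#' selection and as a desk-scale QC/oracle utility.
#'
#' @param contigs contig sequences (same forms as [kmer_index()]).
#' @param k k-mer length.
#' @return tibble with `kmer` (canonical form), `count`, and the first
#'   occurrence's `contig_id`, `position` (0-based) and `forward` flag.
#' @export
count_canonical_kmers <- function(contigs, k) {
  contigs <- .as_contig_set(contigs)
  as_tibble(.cpp_count_kmers(unname(contigs), as.integer(k)))
}

#' Query k-mers against a unique k-mer index
#'
#' Every indexed k-mer (or its reverse complement) returns its stored record.
#' Absent k-mers return `found = FALSE` except with probability about
#' 2^-16, in which case an arbitrary stored record is returned and
#' `fp_collision` is `TRUE` (the flag is available here because the exact
#' key set is retained; a production dictionary could not tell).
#'
#' @param index a `kmer_index`.
#' @param kmers character vector of k-mers, each of length `index$k`.
#' @return tibble with `kmer`, `found`, `contig_id`, `contig`, `position`
#'   (0-based), `strand` (`"+"` if the canonical form equals the contig
#'   forward k-mer), `query_forward` (whether the queried string was the
#'   canonical form) and `fp_collision`.
#' @export
kmer_lookup <- function(index, kmers) {
  stopifnot(inherits(index, "kmer_index"))
  res <- as_tibble(.cpp_lookup(index$ptr, kmers))
  res$kmer <- kmers
  res$contig <- index$contigs$contig[res$contig_id]
  res[c("kmer", "found", "contig_id", "contig", "position", "strand",
        "query_forward", "fp_collision")]
}

#' Measure the empirical false-positive rate of an index
#'
#' Generates `n` uniformly random k-mers with a dedicated xorshift128+
#' generator (independent of R's RNG stream), queries each through the
#' fingerprint path, and counts how many truly absent queries were
#' spuriously accepted. With a 16-bit fingerprint the expected rate is
#' \eqn{1/2^{16} = 0.0000152}.
#'
#' @param index a `kmer_index` (k must be at most 32).
#' @param n number of random queries.
#' @param seed integer seed for the query generator.
#' @return one-row tibble with `n_queries`, `n_present`, `n_absent`,
#'   `n_false_positive`, `fp_rate` and `expected_rate`.
#' @export
fp_rate_experiment <- function(index, n = 1e7, seed = 1L) {
  stopifnot(inherits(index, "kmer_index"))
  res <- .cpp_fp_experiment(index$ptr, as.double(n), as.integer(seed))
  tibble(
    n_queries = res$n_queries,
    n_present = res$n_present,
    n_absent = res$n_absent,
    n_false_positive = res$n_false_positive,
    fp_rate = res$n_false_positive / res$n_absent,
    expected_rate = 2^(-index$fingerprint_bits)
  )
}

#' Persist / restore a unique k-mer index
#'
#' The on-disk format is a single binary file with a versioned header
#' (magic, k, fingerprint bits, key count, contig table) followed by the
#' per-slot key hashes, fingerprints and payload arrays; it round-trips
#' losslessly. Note that a `kmer_index` holds an external pointer and
#' therefore does not survive `saveRDS()`; use these functions instead.
#'
#' @param index a `kmer_index`.
#' @param path file path.
#' @return `write_kmer_index` returns `path` invisibly; `read_kmer_index`
#'   returns the restored `kmer_index`.
#' @export
write_kmer_index <- function(index, path) {
  stopifnot(inherits(index, "kmer_index"))
  .cpp_save_index(index$ptr, path)
  invisible(path)
}

#' @rdname write_kmer_index
#' @export
read_kmer_index <- function(path) {
  .wrap_index(.cpp_load_index(path))
}
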
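# Independent oracles and fixture builders. The oracles deliberately avoid
# the package's code paths: string reverse complement via chartr/rev,
# k-mer enumeration via substring(), window scoring via an anchored
# quadratic scan over data-frame rows.

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

rand_genome <- function(n, seed) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = ""))
}

# exhaustive canonical k-mer counts over a set of sequences
oracle_kmer_counts <- function(seqs, k) {
  all <- unlist(lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < k) return(character())
    w <- substring(toupper(s), 1:(L - k + 1), k:L)
    w[!grepl("[^ACGT]", w)]
  }))
  if (length(all) == 0) return(integer())
  rc <- vapply(all, oracle_revcomp, character(1), USE.NAMES = FALSE)
  canon <- ifelse(all <= rc, all, rc)
  table(canon)
}

# exhaustive single-occurrence table: canonical kmer -> contig/pos/strand
oracle_unique_occurrences <- function(seqs, k) {
  rows <- list()
  for (ci in seq_along(seqs)) {
    s <- toupper(seqs[[ci]])
    L <- nchar(s)
    if (L < k) next
    w <- substring(s, 1:(L - k + 1), k:L)
    ok <- !grepl("[^ACGT]", w)
    rc <- vapply(w, oracle_revcomp, character(1), USE.NAMES = FALSE)
    canon <- ifelse(w <= rc, w, rc)
    rows[[ci]] <- data.frame(kmer = canon[ok], contig_id = ci,
                             position = which(ok) - 1L,
                             strand = ifelse((w <= rc)[ok], "+", "-"))
  }
  occ <- do.call(rbind, rows)
  counts <- table(occ$kmer)
  occ[occ$kmer %in% names(counts)[counts == 1], ]
}

# naive quadratic window scan (anchored at each hit's inferred start)
oracle_window_score <- function(hits, read_len, k) {
  n <- nrow(hits)
  if (n == 0) return(list(score = 0L, ambiguous = FALSE))
  start <- ifelse(hits$strand == "+",
                  hits$coordinate - hits$read_offset,
                  hits$coordinate + hits$read_offset + k - read_len)
  cnt <- integer(n)
  for (i in seq_len(n)) {
    cnt[i] <- sum(hits$contig_id == hits$contig_id[i] &
                    hits$strand == hits$strand[i] &
                    start >= start[i] & start < start[i] + read_len)
  }
  best <- max(cnt)
  anchors <- which(cnt == best)
  o <- anchors[order(hits$contig_id[anchors], hits$strand[anchors],
                     start[anchors])]
  n_loc <- 1L
  if (length(o) > 1) {
    for (i in 2:length(o)) {
      a <- o[i - 1]; b <- o[i]
      same <- hits$contig_id[a] == hits$contig_id[b] &&
        hits$strand[a] == hits$strand[b] && start[b] - start[a] < read_len
      if (!same) n_loc <- n_loc + 1L
    }
  }
  list(score = best, ambiguous = n_loc > 1L)
}

# standard small dataset shared by several tests: a fragmented genome with a
# planted repeat, plus an index over the contigs
small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gen <- simulate_genome(60000, repeats = list(c(length = 2000, copies = 2)),
                             seed = 11)
      frag <- fragment_genome(gen$sequence, n_contigs = 4)
      idx <- kmer_index(setNames(frag$contigs$sequence, frag$contigs$contig),
                        k = 21)
      cache <<- list(genome = gen, frag = frag, idx = idx)
    }
    cache
  }
})

# an error-free FR pair drawn from genome coordinates (0-based start)
perfect_pair <- function(genome, u, insert, read_len = 100) {
  list(qf = substr(genome, u + 1, u + read_len),
       qr = oracle_revcomp(substr(genome, u + insert - read_len + 1, u + insert)))
}
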
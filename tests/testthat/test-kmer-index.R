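test_that("canonical hashing is strand-symmetric and skips non-ACGT windows", {
  # ACGT is its own reverse complement: one hash, forward canonical
  h <- canonical_hashes("ACGT", 4)
  expect_equal(nrow(h), 1L)
  expect_identical(h$offset, 0L)

  # N excludes exactly the windows covering it
  h2 <- canonical_hashes("ACGNT", 2)
  expect_identical(h2$offset, c(0L, 1L))
  h3 <- canonical_hashes("ACNGT", 2)
  expect_identical(h3$offset, c(0L, 3L))

  # hash stream of revcomp(w) is the offset-reversed stream of w
  for (seed in 1:20) {
    w <- rand_genome(30, seed)
    a <- canonical_hashes(w, 21)
    b <- canonical_hashes(oracle_revcomp(w), 21)
    expect_identical(a$hash, rev(b$hash))
  }

  # single-kmer hashes agree with the stream (used implicitly by lookups)
  w <- rand_genome(21, 99)
  expect_identical(canonical_hashes(w, 21)$hash,
                   canonical_hashes(oracle_revcomp(w), 21)$hash)
})

test_that("canonical k-mer counting matches exhaustive enumeration", {
  # homopolymer: one canonical 2-mer, count 3
  cc <- count_canonical_kmers("AAAA", 2)
  expect_equal(nrow(cc), 1L)
  expect_equal(cc$count, 3L)

  # ACG / CGT are reverse complements: one canonical key with count 2
  cc2 <- count_canonical_kmers(c("ACG", "CGT"), 3)
  expect_equal(nrow(cc2), 1L)
  expect_equal(cc2$count, 2L)

  # randomized genomes against the enumeration oracle
  for (seed in 1:5) {
    g <- rand_genome(400, seed)
    seqs <- c(g, substr(g, 50, 120))  # embed a duplicated block
    got <- count_canonical_kmers(seqs, 11)
    want <- oracle_kmer_counts(seqs, 11)
    expect_equal(nrow(got), length(want))
    expect_identical(setNames(as.integer(got$count), got$kmer)[names(want)],
                     setNames(as.integer(want), names(want)))
  }
})

test_that("index stores exactly the frequency-1 canonical k-mers with true payloads", {
  g <- rand_genome(5000, 3)
  dup <- substr(g, 1001, 1800)  # 800 bp exact duplicate
  g2 <- paste0(g, dup)
  idx <- kmer_index(c(chr = g2), k = 21)

  occ <- oracle_unique_occurrences(list(g2), 21)
  expect_equal(idx$n_keys, nrow(occ))

  lk <- kmer_lookup(idx, occ$kmer)
  expect_true(all(lk$found))
  expect_false(any(lk$fp_collision))
  expect_equal(lk$position, occ$position)
  expect_equal(lk$strand, occ$strand)

  # revcomp queries return the same record
  lk2 <- kmer_lookup(idx, vapply(occ$kmer[1:50], oracle_revcomp, character(1)))
  expect_equal(lk2$position, occ$position[1:50])
  expect_equal(lk2$strand, occ$strand[1:50])

  # no key maps inside either copy of the duplicated block's interior
  interior <- substring(dup, 1:(nchar(dup) - 20), 21:nchar(dup))
  lki <- kmer_lookup(idx, interior)
  expect_true(all(!lki$found | lki$fp_collision))
})

test_that("degenerate inputs error clearly", {
  expect_error(kmer_index(c(a = "AAAAAAAAAAAAAAAAAAAAAA"), k = 15),
               "no unique")
  expect_error(kmer_index(c(a = "ACGT"), k = 15), "no unique")
  idx <- small_dataset()$idx
  expect_error(kmer_lookup(idx, "ACGT"), "length")
  expect_error(kmer_index(c(a = rand_genome(100, 1)), k = 10), "between 15 and 256")
})

test_that("construction is invariant to chunking and the index round-trips", {
  frag <- small_dataset()$frag
  contigs <- setNames(frag$contigs$sequence, frag$contigs$contig)
  idx_a <- kmer_index(contigs, k = 21, chunk_size = 5e6)
  idx_b <- kmer_index(contigs, k = 21, chunk_size = 1337)
  expect_equal(idx_a$n_keys, idx_b$n_keys)

  probes <- substring(frag$contigs$sequence[1], 1:200, 21:220)
  expect_identical(kmer_lookup(idx_a, probes), kmer_lookup(idx_b, probes))

  # chunk size must not affect the persisted bytes either
  fa <- tempfile(); fb <- tempfile()
  write_kmer_index(idx_a, fa)
  write_kmer_index(idx_b, fb)
  expect_identical(readBin(fa, "raw", file.size(fa)),
                   readBin(fb, "raw", file.size(fb)))

  # load restores k, contig table and all query answers
  idx_c <- read_kmer_index(fa)
  expect_equal(idx_c$k, idx_a$k)
  expect_equal(idx_c$n_keys, idx_a$n_keys)
  expect_identical(idx_c$contigs, idx_a$contigs)
  expect_identical(kmer_lookup(idx_c, probes), kmer_lookup(idx_a, probes))
  expect_error(read_kmer_index(fb2 <- tempfile(fileext = ".txt")),
               "cannot open")
  writeLines("not an index", fb2)
  expect_error(read_kmer_index(fb2), "magic")
})

test_that("fingerprint false positives occur at roughly 2^-16", {
  # moderate-n sanity check here; the full-depth measurement runs in the
  # acceptance suite
  idx <- small_dataset()$idx
  fp <- fp_rate_experiment(idx, n = 2e6, seed = 5)
  p <- 2^-16
  expect_gt(fp$n_false_positive, 0)
  expect_lt(abs(fp$fp_rate - p), 4 * sqrt(p * (1 - p) / fp$n_absent))
})
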
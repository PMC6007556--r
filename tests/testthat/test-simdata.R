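test_that("genome simulation plants verbatim repeats and is seed-deterministic", {
  g1 <- simulate_genome(20000, repeats = list(c(length = 1000, copies = 3)),
                        seed = 4)
  g2 <- simulate_genome(20000, repeats = list(c(length = 1000, copies = 3)),
                        seed = 4)
  expect_identical(g1$sequence, g2$sequence)
  expect_identical(g1$repeats, g2$repeats)
  g3 <- simulate_genome(20000, repeats = list(c(length = 1000, copies = 3)),
                        seed = 5)
  expect_false(identical(g1$sequence, g3$sequence))

  # all copies are identical blocks at non-overlapping positions
  copies <- substring(g1$sequence, g1$repeats$start, g1$repeats$end)
  expect_equal(length(unique(copies)), 1L)
  iv <- g1$repeats[order(g1$repeats$start), ]
  expect_true(all(iv$start[-1] > iv$end[-nrow(iv)]))

  expect_error(simulate_genome(1000, repeats = list(c(length = 600, copies = 2))),
               "exceed")
})

test_that("repeat interiors contain no unique k-mers after indexing", {
  g <- simulate_genome(30000, repeats = list(c(length = 1500, copies = 2)),
                       seed = 8)
  counts <- oracle_kmer_counts(list(g$sequence), 21)
  r <- g$repeats[1, ]
  interior <- substring(g$sequence, (r$start + 0):(r$end - 20), (r$start + 20):r$end)
  rc <- vapply(interior, oracle_revcomp, character(1), USE.NAMES = FALSE)
  canon <- ifelse(interior <= rc, interior, rc)
  expect_true(all(counts[canon] >= 2))
})

test_that("fragmentation tiles the genome and records the layout", {
  g <- rand_genome(100000, 2)
  fr <- fragment_genome(g, n_contigs = 10)
  expect_equal(nrow(fr$contigs), 10L)
  expect_true(all(nchar(fr$contigs$sequence) == 10000L))
  expect_equal(paste(fr$contigs$sequence, collapse = ""), g)
  expect_equal(fr$layout$start, seq(1L, 90001L, by = 10000L))
  expect_equal(fr$layout$end, seq(10000L, 100000L, by = 10000L))
  # 10 tiles define 9 potential joins
  expect_equal(sum(table(fr$layout$reference) - 1L), 9L)

  # random breakpoints: reproducible under seed, respect the minimum length
  fa <- fragment_genome(g, n_contigs = 8, random = TRUE, seed = 3,
                        min_contig = 2000)
  fb <- fragment_genome(g, n_contigs = 8, random = TRUE, seed = 3,
                        min_contig = 2000)
  expect_identical(fa$layout, fb$layout)
  expect_true(all(nchar(fa$contigs$sequence) >= 2000))
  expect_equal(paste(fa$contigs$sequence, collapse = ""), g)
})

test_that("illumina simulation honours orientation, errors and contamination", {
  g <- rand_genome(50000, 6)
  p <- simulate_illumina_pairs(g, n_pairs = 200, insert_mean = 2000,
                               insert_sd = 100, seed = 7)
  expect_identical(p, simulate_illumina_pairs(g, n_pairs = 200,
                                              insert_mean = 2000,
                                              insert_sd = 100, seed = 7))
  # error-free pairs are exact genome cut-outs in FR orientation
  i <- 5
  expect_equal(p$qf[i], substr(g, p$true_start[i] + 1, p$true_start[i] + 100))
  expect_equal(p$qr[i], oracle_revcomp(substr(
    g, p$true_start[i] + p$true_insert[i] - 99,
    p$true_start[i] + p$true_insert[i])))

  pc <- simulate_illumina_pairs(g, n_pairs = 400, contamination = 0.25,
                                seed = 8)
  expect_gt(sum(pc$contaminant), 50)
  expect_lt(mean(pc$true_insert[pc$contaminant]), 600)

  pe <- simulate_illumina_pairs(g, n_pairs = 50, error_rate = 0.05, seed = 9)
  mm <- mapply(function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
               pe$qf, substring(g, pe$true_start + 1, pe$true_start + 100))
  expect_gt(mean(mm) / 100, 0.02)
  expect_lt(mean(mm) / 100, 0.08)
})

test_that("long-read profiles behave as labelled", {
  g <- rand_genome(60000, 10)
  # error-free reads are exact substrings (or reverse complements)
  lr0 <- simulate_long_reads(g, n_reads = 10, mean_len = 5000, len_sd = 500,
                             error_rate = 0, seed = 11)
  for (i in seq_len(nrow(lr0))) {
    tpl <- substr(g, lr0$true_start[i] + 1, lr0$true_end[i])
    if (lr0$strand[i] == "-") tpl <- oracle_revcomp(tpl)
    expect_identical(lr0$sequence[i], tpl)
  }

  # deletion-dominant ONT-like reads shrink; PacBio-like keep length roughly
  ont <- simulate_long_reads(g, n_reads = 30, mean_len = 5000, len_sd = 200,
                             error_rate = 0.15, profile = "ont", seed = 12)
  pb <- simulate_long_reads(g, n_reads = 30, mean_len = 5000, len_sd = 200,
                            error_rate = 0.15, profile = "pacbio", seed = 12)
  ont_ratio <- mean(nchar(ont$sequence) / ont$template_len)
  pb_ratio <- mean(nchar(pb$sequence) / pb$template_len)
  # ont: -60% del +15% ins of 15% errors => ~6.7% shrink; pacbio: +1.5% growth
  expect_lt(ont_ratio, 0.96)
  expect_gt(pb_ratio, 1.0)

  expect_identical(ont$sequence,
                   simulate_long_reads(g, n_reads = 30, mean_len = 5000,
                                       len_sd = 200, error_rate = 0.15,
                                       profile = "ont", seed = 12)$sequence)
})

test_that("simulate_dataset bundles a coherent ground-truth package", {
  cfg <- sim_config(genome_length = 40000, repeats = list(),
                    n_contigs = 4,
                    illumina = list(n_pairs = 50L),
                    longread = list(n_reads = 5L, mean_len = 3000,
                                    len_sd = 300),
                    seed = 2)
  ds <- simulate_dataset(cfg)
  expect_equal(nchar(ds$genome$sequence), 40000L)
  expect_equal(nrow(ds$contigs), 4L)
  expect_equal(nrow(ds$pairs), 50L)
  expect_equal(nrow(ds$long_reads), 5L)
  expect_equal(paste(ds$contigs$sequence, collapse = ""), ds$genome$sequence)
  expect_error(sim_config(longread = list(profile = "nanopore")))
})
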
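test_that("hit collection respects capacity, canonical lookup, and repeats", {
  ds <- small_dataset()
  idx <- ds$idx
  contig1 <- ds$frag$contigs$sequence[1]

  # error-free read from a unique region: capacity consecutive hits
  read <- substr(contig1, 501, 600)
  h <- collect_hits(read, idx, capacity = 10)
  expect_equal(nrow(h), 10L)
  expect_true(all(h$contig_id == 1L))
  expect_identical(h$coordinate, 500L + 0:9)
  expect_true(all(h$strand == "+"))

  # reverse-complemented read: hits flagged as reverse matches
  hrc <- collect_hits(oracle_revcomp(read), idx, capacity = 10)
  expect_equal(nrow(hrc), 10L)
  expect_true(all(hrc$strand == "-"))

  # all-N read yields nothing; short read yields nothing
  expect_equal(nrow(collect_hits(strrep("N", 100), idx)), 0L)
  expect_equal(nrow(collect_hits("ACGT", idx)), 0L)

  # read wholly inside a planted repeat has no unique k-mers
  rep1 <- ds$genome$repeats[1, ]
  rep_read <- substr(ds$genome$sequence, rep1$start + 500, rep1$start + 599)
  hr <- collect_hits(rep_read, idx, capacity = 10)
  expect_true(nrow(hr) <= sum(kmer_lookup(idx, substring(rep_read, 1:80, 21:100))$fp_collision))
})

test_that("window scoring agrees with the naive quadratic oracle", {
  withr::with_seed(42, {
    for (case in 1:200) {
      n <- sample(0:12, 1)
      hits <- tibble::tibble(
        contig_id = sample(1:3, n, TRUE),
        coordinate = sample(0:400, n, TRUE),
        strand = sample(c("+", "-"), n, TRUE),
        read_offset = sample(0:79, n, TRUE)
      )
      got <- score_read(hits, read_length = 100, k = 21)
      want <- oracle_window_score(hits, 100, 21)
      expect_equal(got$score, want$score)
      expect_equal(got$ambiguous, want$ambiguous)
      expect_equal(got$effective_score,
                   if (want$ambiguous) 0L else want$score)
    }
  })
  expect_equal(score_read(tibble::tibble(contig_id = integer(),
                                         coordinate = integer(),
                                         strand = character(),
                                         read_offset = integer()),
                          100, k = 21)$score, 0L)
})

test_that("ties at distinct locations are ambiguous, overlapping windows are not", {
  # 5 hits at contig 1 and 5 at contig 2: ambiguous
  hits <- tibble::tibble(
    contig_id = rep(1:2, each = 5),
    coordinate = rep(100 + (0:4) * 10, 2),
    strand = "+",
    read_offset = rep((0:4) * 10, 2)
  )
  s <- score_read(hits, 100, k = 21)
  expect_true(s$ambiguous)
  expect_equal(s$effective_score, 0L)

  # same hits all on one contig at one location: unambiguous
  hits1 <- hits
  hits1$contig_id <- 1L
  hits1$coordinate <- c(100 + (0:4) * 10, 100 + (0:4) * 10)
  hits1$read_offset <- rep((0:4) * 10, 2)
  s1 <- score_read(hits1, 100, k = 21)
  expect_false(s1$ambiguous)
  expect_equal(s1$score, 10L)
})

test_that("perfect pairs are placed at their true location and orientation", {
  ds <- small_dataset()
  g <- ds$genome$sequence
  idx <- ds$idx
  # contig 1 spans genome [1, 15000]; pick a fragment clear of the repeat
  layout <- ds$frag$layout
  rep_iv <- ds$genome$repeats
  u <- 2000
  pr <- perfect_pair(g, u, 3000)
  pl <- map_pair(pr$qf, pr$qr, idx)
  expect_false(is.null(pl))
  expect_equal(pl$f_start, u)
  expect_equal(pl$r_start, u + 3000 - 100)
  expect_equal(pl$orientation, "FR")
  expect_equal(pl$observed_insert, 3000L)
  expect_false(pl$rescued)

  # forward read entirely repetitive: forward gate fails, pair dropped
  rep_read <- substr(g, rep_iv$start[1] + 300, rep_iv$start[1] + 399)
  expect_null(map_pair(rep_read, pr$qr, idx))
})

test_that("mapping the reverse-complemented pair mirrors the placement", {
  ds <- small_dataset()
  g <- ds$genome$sequence
  pr <- perfect_pair(g, 20500, 2800)
  a <- map_pair(pr$qf, pr$qr, ds$idx)
  b <- map_pair(oracle_revcomp(pr$qf), oracle_revcomp(pr$qr), ds$idx)
  expect_false(is.null(b))
  expect_equal(b$f_contig_id, a$f_contig_id)
  expect_equal(b$f_start, a$f_start)
  expect_equal(b$f_strand, ifelse(a$f_strand == "+", "-", "+"))
  expect_equal(b$r_strand, ifelse(a$r_strand == "+", "-", "+"))
  expect_equal(b$observed_insert, a$observed_insert)
  expect_equal(b$orientation, "RF")  # mirrored innie reads outward by labels
})

test_that("pair rescue honours score, distance and orientation constraints", {
  ds <- small_dataset()
  g <- ds$genome$sequence
  idx <- ds$idx
  lib <- library_params(3000, 150, "FR")
  u <- 31000          # genome offset; contig_003 starts at offset 30000
  u_local <- 1000
  pr <- perfect_pair(g, u, 3000)
  # corrupt the mate so only its first 24 bases are intact: 4 clean 21-mers
  weak <- paste0(substr(pr$qr, 1, 24),
                 paste(rep("N", 76), collapse = ""))

  # without a library, rescue is skipped and the pair is dropped
  expect_null(map_pair(pr$qf, weak, idx, mapper_params(lib = NULL)))

  # with the library, the mate is rescued at score 4
  pl <- map_pair(pr$qf, weak, idx, mapper_params(lib = lib))
  expect_false(is.null(pl))
  expect_true(pl$rescued)
  expect_equal(pl$r_score, 4L)
  expect_equal(pl$f_start, u_local)
  expect_equal(pl$f_contig_id, 3L)

  # a rescue threshold above the available hits rejects it
  expect_null(map_pair(pr$qf, weak, idx,
                       mapper_params(lib = lib, min_rescue_score = 5)))

  # right distance but wrong orientation (mate not reverse-complemented)
  weak_ff <- paste0(substr(oracle_revcomp(pr$qr), 77, 100),
                    paste(rep("N", 76), collapse = ""))
  expect_null(map_pair(pr$qf, weak_ff, idx, mapper_params(lib = lib)))

  # hits implying an insert far outside mu +/- 3 sd
  far <- substr(g, u + 9000 + 1, u + 9000 + 24)
  weak_far <- paste0(oracle_revcomp(far), paste(rep("N", 76), collapse = ""))
  expect_null(map_pair(pr$qf, weak_far, idx, mapper_params(lib = lib)))

  # direct rescue_pair API
  fixed <- score_read(collect_hits(pr$qf, idx, 10), 100)
  rs <- rescue_pair(fixed, 100, weak, idx, mapper_params(lib = lib))
  expect_false(is.null(rs))
  expect_equal(rs$score, 4L)
  expect_null(rescue_pair(fixed, 100, weak, idx, mapper_params(lib = NULL)))
})

test_that("raising the report threshold never increases reported pairs", {
  ds <- small_dataset()
  g <- ds$genome$sequence
  withr::with_seed(7, {
    n <- 150
    ins <- pmax(200L, as.integer(round(rnorm(n, 3000, 300))))
    u <- vapply(ins, function(i) sample.int(nchar(g) - i, 1L), integer(1))
    pairs <- tibble::tibble(
      qf = substring(g, u + 1, u + 100),
      qr = vapply(seq_len(n), function(i)
        oracle_revcomp(substring(g, u[i] + ins[i] - 99, u[i] + ins[i])),
        character(1))
    )
  })
  counts <- vapply(c(3L, 5L, 7L, 9L), function(ms) {
    sum(map_read_pairs(pairs, ds$idx,
                       mapper_params(min_report_score = ms),
                       keep_sequences = FALSE)$placed)
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})
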
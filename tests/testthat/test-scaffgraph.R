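test_that("graph edges recover true adjacencies with correct orientation", {
  ds <- small_dataset()
  g <- ds$genome$sequence
  pairs <- simulate_illumina_pairs(g, n_pairs = 4000, insert_mean = 3000,
                                   insert_sd = 300, seed = 31)
  lib <- library_params(3000, 300, "FR")
  pl <- map_read_pairs(pairs, ds$idx, mapper_params(lib = lib),
                       keep_sequences = FALSE)
  edges <- build_scaffold_graph(pl, lib, ds$idx)

  # contigs tile the genome: the only true links are consecutive ids
  want <- sprintf("contig_%03d", 1:4)
  expect_setequal(paste(edges$contig_u, edges$contig_v),
                  paste(want[1:3], want[2:4]))
  expect_true(all(edges$orientation == "++"))
  expect_true(all(edges$weight >= 3))
  # tiling contigs: true gap 0, estimates within a few library sd / sqrt(n)
  expect_true(all(abs(edges$distance_estimate) < 300))

  # all-within-contig placements give an empty edge set
  within <- pl[pl$placed & pl$f_contig_id == pl$r_contig_id, ]
  expect_equal(nrow(build_scaffold_graph(within, lib, ds$idx)), 0L)

  # a single spanning pair is below the default weight threshold
  one <- pl[pl$placed & pl$f_contig_id != pl$r_contig_id, ][1, ]
  expect_equal(nrow(build_scaffold_graph(one, lib, ds$idx)), 0L)
  expect_equal(nrow(build_scaffold_graph(one, lib, ds$idx, min_weight = 1)), 1L)

  # non-FR libraries are refused
  expect_error(build_scaffold_graph(pl, library_params(3000, 300, "RF"),
                                    ds$idx), "forward-reverse")
})

test_that("join classification assigns the bit-wise error flags", {
  truth <- tibble::tibble(
    reference = c("r1", "r1", "r1", "r2"),
    contig = c("A", "B", "C", "D"),
    start = c(1L, 1001L, 2101L, 1L),
    end = c(1000L, 2100L, 3000L, 500L),
    strand = c("+", "+", "-", "+")
  )
  perfect <- tibble::tibble(
    scaffold = "s1", position = 1:3, contig = c("A", "B", "C"),
    orientation = c("+", "+", "-"), gap_after = c(0L, 0L, NA)
  )
  expect_true(all(classify_joins(perfect, truth, tolerance = 10)$flag == 0L))

  # the whole scaffold reverse-complemented is still all-correct
  flipped <- tibble::tibble(
    scaffold = "s1", position = 1:3, contig = c("C", "B", "A"),
    orientation = c("+", "-", "-"), gap_after = c(0L, 0L, NA)
  )
  expect_true(all(classify_joins(flipped, truth, tolerance = 10)$flag == 0L))

  # one contig's orientation inverted: flag 1 on its joins
  j1 <- classify_joins(perturb_scaffolds(perfect, flip = "B"), truth,
                       tolerance = 10)
  expect_equal(j1$flag, c(1L, 1L))

  # join across two reference sequences: flag 2
  cross <- tibble::tibble(scaffold = "s1", position = 1:2,
                          contig = c("C", "D"), orientation = c("-", "+"),
                          gap_after = c(0L, NA))
  expect_equal(classify_joins(cross, truth, tolerance = 10)$flag, 2L)

  # wrong distance: flag 4; with a flip as well: 5
  j4 <- classify_joins(perturb_scaffolds(perfect, gap_add = c(A = 5000)),
                       truth, tolerance = 10)
  expect_equal(j4$flag, c(4L, 0L))
  j5 <- classify_joins(perturb_scaffolds(perfect, flip = "B",
                                         gap_add = c(A = 5000)),
                       truth, tolerance = 10)
  expect_equal(j5$flag[1], 5L)

  # wrong order: flag 8; wrong order and distance: 12
  two <- perfect[perfect$contig %in% c("A", "B"), ]
  swapped <- perturb_scaffolds(two, swap = c("A", "B"))
  expect_equal(classify_joins(swapped, truth, tolerance = 10)$flag, 8L)
  j12 <- classify_joins(perturb_scaffolds(swapped, gap_add = c(B = 5000)),
                        truth, tolerance = 10)
  expect_equal(j12$flag, 12L)

  # flags decompose into their component checks
  all_j <- dplyr::bind_rows(j1, j4, j5, j12)
  expect_equal(all_j$flag,
               (!all_j$orientation_ok) * 1L + (!all_j$distance_ok) * 4L +
                 (!all_j$order_ok) * 8L)

  expect_error(classify_joins(tibble::tibble(scaffold = "s", position = 1L,
                                             contig = "ZZZ",
                                             orientation = "+",
                                             gap_after = NA),
                              truth), "absent")
})

test_that("recall, precision and F-score follow their definitions", {
  expect_equal(join_f_score(10, 10, 0)[, c("recall", "precision", "f_score")],
               tibble::tibble(recall = 1, precision = 1, f_score = 1))
  z <- join_f_score(10, 0, 5)
  expect_equal(c(z$recall, z$precision, z$f_score), c(0, 0, 0))
  m <- join_f_score(10, 6, 2)
  expect_equal(m$recall, 0.6)
  expect_equal(m$precision, 0.75)
  expect_equal(m$f_score, 2 * 0.45 / 1.35)
  expect_error(join_f_score(0, 0, 0), "positive")
  expect_error(join_f_score(5, 6, 0))
})

test_that("scaffold evaluation summarises joins against the truth layout", {
  ds <- small_dataset()
  truth <- ds$frag$layout
  sc <- layout_to_scaffolds(truth)
  ev <- evaluate_scaffolds(sc, truth)
  expect_s3_class(ev, "join_evaluation")
  s <- glance(ev)
  expect_equal(c(s$P, s$TP, s$FP), c(3, 3, 0))
  expect_equal(s$f_score, 1)
  expect_equal(nrow(tidy(ev)), 3)

  # one flipped contig costs one join... and both joins touching it
  bad <- perturb_scaffolds(sc, flip = "contig_002")
  s2 <- glance(evaluate_scaffolds(bad, truth))
  expect_equal(s2$TP, 1)
  expect_equal(s2$FP, 2)
  expect_lt(s2$f_score, 1)
})

test_that("layout, scaffold and edge tables round-trip through TSV", {
  d <- withr::local_tempdir()
  ds <- small_dataset()
  layout <- ds$frag$layout
  write_layout(layout, f <- file.path(d, "layout.tsv"))
  expect_equal(read_layout(f), layout)
  sc <- layout_to_scaffolds(layout)
  write_scaffolds(sc, f2 <- file.path(d, "scaf.tsv"))
  expect_equal(read_scaffolds(f2), sc)
  edges <- tibble::tibble(contig_u = "a", contig_v = "b", orientation = "++",
                          weight = 5L, distance_estimate = 12.5)
  write_edges(edges, f3 <- file.path(d, "edges.tsv"))
  expect_equal(read_edges(f3), edges, ignore_attr = TRUE)
})
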
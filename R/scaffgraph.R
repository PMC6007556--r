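#' Build a scaffolding graph from pair placements
#'
#' Read pairs whose two reads map uniquely to different contigs carry the
#' linking information: each such pair supports an edge between its two
#' contigs, with the edge recording the number of supporting pairs
#' (weight), the relative orientation of the contigs, and the estimated
#' gap between them. The gap implied by one pair is
#' `mean_insert - d_u - d_v`, where `d` is the distance from each read's
#' start to the contig end it points at (`length - start` for a `+` read,
#' `start + read_len` for a `-` read); the edge's distance estimate is the
#' mean over its supporting pairs. Edges supported by fewer than
#' `min_weight` pairs are dropped.
#'
#' Orientation convention: an edge is canonicalised so `contig_u` is the
#' contig with the smaller id; `orientation` is two characters giving the
#' orientation of u then v in the layout "u then v" (so `"++"` means both
#' contigs in forward orientation, as for a collinear genome). This
#' assumes a forward-reverse library; the construction errors out for
#' other orientations.
#'
#' @param placements placement tibble from [map_read_pairs()] or
#'   [read_sam_placements()].
#' @param lib a [library_params()] for the library the placements came
#'   from (FR orientation required).
#' @param index a `kmer_index` or its `contigs` tibble.
#' @param min_weight minimum supporting pairs per kept edge.
#' @return tibble of class `scaffold_graph`: `contig_u`, `contig_v`
#'   (names), `orientation`, `weight`, `distance_estimate`.
#' @export
build_scaffold_graph <- function(placements, lib, index, min_weight = 3L) {
  stopifnot(inherits(lib, "library_params"))
  if (lib$orientation != "FR") {
    stop("scaffold-graph construction expects a forward-reverse library")
  }
  contigs <- if (inherits(index, "kmer_index")) index$contigs else index
  p <- placements[placements$placed &
                    placements$f_contig_id != placements$r_contig_id, ,
                  drop = FALSE]
  empty <- tibble(contig_u = character(), contig_v = character(),
                  orientation = character(), weight = integer(),
                  distance_estimate = double())
  class(empty) <- c("scaffold_graph", class(empty))
  if (nrow(p) == 0) return(empty)

  end_dist <- function(contig_id, start, strand, read_len) {
    ifelse(strand == "+",
           contigs$length[contig_id] - start,
           start + read_len)
  }
  d_f <- end_dist(p$f_contig_id, p$f_start, p$f_strand, p$f_read_len)
  d_r <- end_dist(p$r_contig_id, p$r_start, p$r_strand, p$r_read_len)
  gap <- lib$mean_insert - d_f - d_r

  # layout "forward-read contig first": orientations (s_f, flip(s_r));
  # canonicalise on contig id, reverse-complementing the layout if swapped
  swap <- p$f_contig_id > p$r_contig_id
  u <- ifelse(swap, p$r_contig_id, p$f_contig_id)
  v <- ifelse(swap, p$f_contig_id, p$r_contig_id)
  ou <- ifelse(swap, p$r_strand, p$f_strand)             # read strand on u
  ov <- ifelse(swap, p$f_strand, p$r_strand)             # read strand on v
  # u left: its read must point right -> orientation = read strand;
  # v right: its read points back -> orientation = flipped read strand
  orient <- paste0(ou, .flip_strand(ov))

  edges <- tibble(u = u, v = v, orientation = orient, gap = gap) |>
    dplyr::group_by(.data$u, .data$v, .data$orientation) |>
    dplyr::summarise(weight = dplyr::n(),
                     distance_estimate = mean(.data$gap), .groups = "drop") |>
    dplyr::filter(.data$weight >= min_weight) |>
    dplyr::transmute(contig_u = contigs$contig[.data$u],
                     contig_v = contigs$contig[.data$v],
                     orientation = .data$orientation,
                     weight = as.integer(.data$weight),
                     distance_estimate = .data$distance_estimate)
  class(edges) <- c("scaffold_graph", class(edges))
  edges
}

#' Plot a scaffolding graph
#'
#' @param object a `scaffold_graph` tibble.
#' @param ... unused.
#' @return a ggplot object: contigs on a circle, edges weighted by support.
#' @export
autoplot.scaffold_graph <- function(object, ...) {
  nodes <- sort(unique(c(object$contig_u, object$contig_v)))
  ang <- seq(0, 2 * pi, length.out = length(nodes) + 1)[seq_along(nodes)]
  nd <- tibble(contig = nodes, x = cos(ang), y = sin(ang))
  ed <- dplyr::mutate(object,
                      x = nd$x[match(.data$contig_u, nd$contig)],
                      y = nd$y[match(.data$contig_u, nd$contig)],
                      xend = nd$x[match(.data$contig_v, nd$contig)],
                      yend = nd$y[match(.data$contig_v, nd$contig)])
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = ed,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend,
                                       linewidth = .data$weight),
                          colour = "grey50") +
    ggplot2::geom_point(data = nd, ggplot2::aes(x = .data$x, y = .data$y),
                        size = 3, colour = "steelblue") +
    ggplot2::geom_text(data = nd,
                       ggplot2::aes(x = .data$x * 1.12, y = .data$y * 1.12,
                                    label = .data$contig), size = 3) +
    ggplot2::scale_linewidth(range = c(0.3, 2)) +
    ggplot2::coord_equal() + ggplot2::theme_void()
}

#' Classify scaffold joins against a true layout
#'
#' Each adjacent contig pair inside a scaffold is compared with the true
#' layout and assigned a bit-wise error flag: 0 = correct pair; 1 =
#' same reference but wrong relative orientation; 2 = contigs from
#' different reference sequences; 4 = same reference but wrong distance
#' apart; 8 = same reference but wrong order; composites add (5 = 4+1,
#' 12 = 8+4). The distance check accepts a join when the claimed gap is
#' within `tolerance` of the true gap.
#'
#' @param scaffolds tibble with columns `scaffold`, `position` (1..n
#'   within scaffold), `contig`, `orientation` (`"+"`/`"-"`), `gap_after`
#'   (claimed gap to the next contig; the last row's value is ignored).
#' @param truth true layout tibble: `reference`, `contig`, `start`, `end`
#'   (1-based, inclusive), `strand`.
#' @param tolerance distance tolerance in bases; the default
#'   `max(1000, 3 * lib_sd)` follows the common evaluation practice of
#'   allowing a kilobase or three standard deviations of the library.
#' @param lib_sd library sd feeding the default tolerance.
#' @return tibble with one row per join: `scaffold`, `contig_a`,
#'   `contig_b`, `flag`, plus logical columns `orientation_ok`,
#'   `order_ok`, `distance_ok`.
#' @export
classify_joins <- function(scaffolds, truth, tolerance = NULL, lib_sd = 0) {
  if (is.null(tolerance)) tolerance <- max(1000, 3 * lib_sd)
  missing <- setdiff(scaffolds$contig, truth$contig)
  if (length(missing) > 0) {
    stop("contigs absent from the truth layout: ",
         paste(head(missing, 5), collapse = ", "))
  }
  sc <- scaffolds[order(scaffolds$scaffold, scaffolds$position), ]
  tr <- truth[match(sc$contig, truth$contig), ]
  n <- nrow(sc)
  joins <- list()
  ji <- 0L
  for (i in seq_len(n - 1L)) {
    if (sc$scaffold[i] != sc$scaffold[i + 1L]) next
    a <- i; b <- i + 1L
    same_ref <- tr$reference[a] == tr$reference[b]
    if (!same_ref) {
      flag <- 2L; orient_ok <- NA; order_ok <- NA; dist_ok <- NA
    } else {
      # relative orientation matches iff flips agree
      flip_a <- sc$orientation[a] != tr$strand[a]
      flip_b <- sc$orientation[b] != tr$strand[b]
      orient_ok <- flip_a == flip_b
      # order is only assessable when the join's orientation sense is
      # consistent: the shared flip gives the traversal direction (so a
      # whole reverse-complemented scaffold is still correct); with mixed
      # flips the direction is undefined and order is not additionally
      # penalised (hence no 1+8 composites, matching the flag vocabulary)
      order_ok <- if (!orient_ok) TRUE else if (!flip_a)
        tr$start[b] > tr$start[a] else tr$start[b] < tr$start[a]
      true_gap <- if (tr$start[b] > tr$start[a]) {
        tr$start[b] - tr$end[a] - 1L
      } else {
        tr$start[a] - tr$end[b] - 1L
      }
      claimed <- sc$gap_after[a]
      if (is.na(claimed)) claimed <- 0
      dist_ok <- abs(claimed - true_gap) <= tolerance
      flag <- (!orient_ok) * 1L + (!dist_ok) * 4L + (!order_ok) * 8L
    }
    ji <- ji + 1L
    joins[[ji]] <- tibble(scaffold = sc$scaffold[a],
                          contig_a = sc$contig[a], contig_b = sc$contig[b],
                          flag = flag, orientation_ok = orient_ok,
                          order_ok = order_ok, distance_ok = dist_ok)
  }
  if (ji == 0L) {
    return(tibble(scaffold = character(), contig_a = character(),
                  contig_b = character(), flag = integer(),
                  orientation_ok = logical(), order_ok = logical(),
                  distance_ok = logical()))
  }
  dplyr::bind_rows(joins)
}

#' Recall, precision and F-score over scaffold joins
#'
#' `recall = TP / P`, `precision = TP / (TP + FP)` and the F-score is
#' their harmonic mean, defined as 0 when no join is correct. P is the
#' number of potential joins, i.e. truly adjacent contig pairs in the
#' reference layout.
#'
#' @param P potential joins; must be positive.
#' @param TP correct joins made.
#' @param FP incorrect joins made.
#' @return one-row tibble: `P`, `TP`, `FP`, `recall`, `precision`,
#'   `f_score`.
#' @export
join_f_score <- function(P, TP, FP) {
  if (P <= 0) stop("P must be positive (no potential joins defined)")
  stopifnot(TP >= 0, TP <= P, FP >= 0)
  recall <- TP / P
  precision <- if (TP + FP > 0) TP / (TP + FP) else 0
  f <- if (TP > 0) 2 * recall * precision / (recall + precision) else 0
  tibble(P = P, TP = TP, FP = FP, recall = recall, precision = precision,
         f_score = f)
}

#' Evaluate scaffolds against a true layout
#'
#' Runs [classify_joins()] and summarises the result: TP = joins flagged
#' 0, FP = all other joins made, P = adjacent contig pairs in the truth
#' layout.
#'
#' @inheritParams classify_joins
#' @return object of class `join_evaluation` with elements `joins` (the
#'   per-join tibble) and `summary` (from [join_f_score()]); `tidy()`
#'   returns the joins, `glance()` the summary.
#' @export
evaluate_scaffolds <- function(scaffolds, truth, tolerance = NULL, lib_sd = 0) {
  joins <- classify_joins(scaffolds, truth, tolerance, lib_sd)
  P <- sum(vapply(split(truth, truth$reference), nrow, 1L) - 1L)
  TP <- sum(joins$flag == 0L)
  FP <- nrow(joins) - TP
  structure(list(joins = joins, summary = join_f_score(P, TP, FP)),
            class = "join_evaluation")
}

#' @export
print.join_evaluation <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<join_evaluation> P=%d TP=%d FP=%d  recall=%.3f precision=%.3f F=%.3f\n",
    s$P, s$TP, s$FP, s$recall, s$precision, s$f_score))
  if (nrow(x$joins) > 0) {
    tab <- table(x$joins$flag)
    cat("  flags:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
        "\n")
  }
  invisible(x)
}

#' @export
tidy.join_evaluation <- function(x, ...) x$joins

#' @export
glance.join_evaluation <- function(x, ...) x$summary

#' Read / write layout, scaffold and edge tables
#'
#' Plain TSV interchange: a layout file has columns `reference`, `contig`,
#' `start`, `end`, `strand`; a scaffold file `scaffold`, `position`,
#' `contig`, `orientation`, `gap_after`; an edge file `contig_u`,
#' `contig_v`, `orientation`, `weight`, `distance_estimate`.
#'
#' @param x tibble to write.
#' @param path file path.
#' @return read functions return tibbles; write functions return `path`
#'   invisibly.
#' @export
read_layout <- function(path) {
  readr_tsv(path, c(reference = "character", contig = "character",
                    start = "integer", end = "integer", strand = "character"))
}

#' @rdname read_layout
#' @export
write_layout <- function(x, path) write_tsv_plain(x, path)

#' @rdname read_layout
#' @export
read_scaffolds <- function(path) {
  readr_tsv(path, c(scaffold = "character", position = "integer",
                    contig = "character", orientation = "character",
                    gap_after = "numeric"))
}

#' @rdname read_layout
#' @export
write_scaffolds <- function(x, path) write_tsv_plain(x, path)

#' @rdname read_layout
#' @export
read_edges <- function(path) {
  readr_tsv(path, c(contig_u = "character", contig_v = "character",
                    orientation = "character", weight = "integer",
                    distance_estimate = "numeric"))
}

#' @rdname read_layout
#' @export
write_edges <- function(x, path) write_tsv_plain(x, path)

readr_tsv <- function(path, cols) {
  map <- c(character = "c", integer = "i", numeric = "d")
  types <- paste(map[unname(cols)], collapse = "")
  readr::read_tsv(path, col_types = types)
}

write_tsv_plain <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
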
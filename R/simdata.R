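#' Simulation configuration
#'
#' Bundles the knobs of the synthetic-data generator. The defaults define
#' the package's reference study conditions: a 1 Mb uniform-random genome
#' with one 5 kb repeat planted in 3 identical copies, fragmented into 10
#' contigs; an Illumina-like forward-reverse mate-pair library of 100 bp
#' reads at insert 3000 +/- 300; and long reads of mean length 10 kb with
#' a 15\% total error rate (the going rate for uncorrected long reads),
#' deletion-dominant for the ONT-like profile and substitution-dominant
#' for the PacBio-like profile.
#'
#' @param genome_length genome size in bases.
#' @param repeats list of `c(length =, copies =)` exact repeats to plant.
#' @param n_contigs number of contigs the genome is fragmented into.
#' @param illumina list: `read_len`, `insert_mean`, `insert_sd`,
#'   `n_pairs`, `error_rate` (per-base substitution), `contamination`
#'   (fraction of short-insert wrong-orientation pairs).
#' @param longread list: `mean_len`, `len_sd`, `n_reads`, `error_rate`,
#'   `profile` (`"ont"` or `"pacbio"`).
#' @param seed integer seed; every generator below is deterministic given
#'   it (R's default Mersenne-Twister stream).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 1e6,
                       repeats = list(c(length = 5000, copies = 3)),
                       n_contigs = 10,
                       illumina = list(),
                       longread = list(),
                       seed = 1L) {
  ill <- modifyList(list(read_len = 100L, insert_mean = 3000, insert_sd = 300,
                         n_pairs = 10000L, error_rate = 0,
                         contamination = 0), illumina)
  lr <- modifyList(list(mean_len = 10000, len_sd = 2000, n_reads = 200L,
                        error_rate = 0.15, profile = "ont"), longread)
  stopifnot(genome_length > 0, n_contigs >= 1,
            ill$contamination >= 0, ill$contamination <= 1,
            lr$profile %in% c("ont", "pacbio"))
  structure(list(genome_length = genome_length, repeats = repeats,
                 n_contigs = n_contigs, illumina = ill, longread = lr,
                 seed = as.integer(seed)),
            class = "sim_config")
}

.rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a genome with planted exact repeats
#'
#' Bases are i.i.d. uniform; each repeat family is one random sequence
#' copied verbatim to randomly chosen non-overlapping positions
#' (overwriting the background), so repeat interiors contain no unique
#' k-mers once k is below the repeat length.
#'
#' @param genome_length genome size, bases.
#' @param repeats list of `c(length =, copies =)` entries.
#' @param seed integer seed (`NULL` to use the current RNG state).
#' @return list with `sequence` (a string) and `repeats` (tibble:
#'   `repeat_id`, `copy`, `start`, `end`, 1-based inclusive).
#' @export
simulate_genome <- function(genome_length = 1e6,
                            repeats = list(c(length = 5000, copies = 3)),
                            seed = NULL) {
  run <- function() {
    total_rep <- sum(vapply(repeats, function(r) r[["length"]] * r[["copies"]], 1))
    if (total_rep > genome_length) stop("planted repeats exceed the genome length")
    g <- .rand_dna(genome_length)
    placed <- tibble(repeat_id = integer(), copy = integer(),
                     start = integer(), end = integer())
    for (ri in seq_along(repeats)) {
      len <- repeats[[ri]][["length"]]
      copies <- repeats[[ri]][["copies"]]
      if (copies < 1) next
      unit <- .rand_dna(len)
      for (ci in seq_len(copies)) {
        for (try in 1:10000) {
          s <- sample.int(genome_length - len + 1L, 1L)
          e <- s + len - 1L
          if (!any(placed$start <= e & placed$end >= s)) break
          if (try == 10000) stop("cannot place repeats without overlap")
        }
        substr(g, s, e) <- unit
        placed <- dplyr::bind_rows(placed,
                                   tibble(repeat_id = ri, copy = ci,
                                          start = s, end = e))
      }
    }
    list(sequence = g, repeats = placed)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Fragment a genome into contigs with a known layout
#'
#' Cuts the genome into contiguous, non-overlapping tiles (equal-sized by
#' default, or at supplied/random breakpoints) and records the true
#' layout, which downstream join evaluation uses as ground truth. With
#' `n` contigs the layout defines `n - 1` potential joins.
#'
#' @param genome genome string (or the list from [simulate_genome()]).
#' @param n_contigs number of tiles when `breakpoints` is `NULL`.
#' @param breakpoints optional sorted vector of internal cut positions
#'   (a cut after base i, 1-based); overrides `n_contigs`.
#' @param random sample `n_contigs - 1` random breakpoints instead of
#'   equal tiles (at least `min_contig` bases apart).
#' @param min_contig minimum contig length under `random`.
#' @param seed integer seed for `random`.
#' @param reference name recorded in the layout.
#' @return list with `contigs` (tibble `contig`, `sequence`) and `layout`
#'   (tibble `reference`, `contig`, `start`, `end`, `strand`).
#' @export
fragment_genome <- function(genome, n_contigs = 10, breakpoints = NULL,
                            random = FALSE, min_contig = 1000, seed = NULL,
                            reference = "genome") {
  if (is.list(genome)) genome <- genome$sequence
  L <- nchar(genome)
  if (is.null(breakpoints)) {
    if (random) {
      pick <- function() {
        repeat {
          bp <- sort(sample.int(L - 1L, n_contigs - 1L))
          if (all(diff(c(0L, bp, L)) >= min_contig)) return(bp)
        }
      }
      breakpoints <- if (is.null(seed)) pick() else withr::with_seed(seed, pick())
    } else {
      breakpoints <- round(seq_len(n_contigs - 1L) * (L / n_contigs))
    }
  }
  bounds <- c(0L, as.integer(breakpoints), L)
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1]
  ids <- sprintf("contig_%03d", seq_along(starts))
  list(
    contigs = tibble(contig = ids,
                     sequence = substring(genome, starts, ends)),
    layout = tibble(reference = reference, contig = ids,
                    start = starts, end = ends, strand = "+")
  )
}

# per-base substitutions at `rate`, vectorised over reads
.add_substitutions <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  bases <- c("A", "C", "G", "T")
  vapply(seqs, function(s) {
    n <- nchar(s)
    hit <- which(runif(n) < rate)
    if (length(hit) == 0) return(s)
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    cur <- match(ch[hit], bases)
    ch[hit] <- bases[((cur - 1L + sample.int(3L, length(hit), replace = TRUE)) %% 4L) + 1L]
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate an Illumina-like mate-pair library
#'
#' Draws fragment (outer insert) sizes from a normal distribution
#' truncated at twice the read length, places fragments uniformly on the
#' genome, and emits forward-reverse pairs: the forward read is the
#' fragment's left end, the reverse read the reverse complement of its
#' right end. A `contamination` fraction of pairs mimics
#' circularisation failures: short inserts (normal, mean 300, sd 50) in
#' reverse-forward (outward) orientation. Per-base substitution errors
#' are applied at `error_rate`.
#'
#' @param genome genome string (or [simulate_genome()] output).
#' @param read_len read length, bases.
#' @param insert_mean,insert_sd insert-size distribution.
#' @param n_pairs number of pairs.
#' @param error_rate per-base substitution probability.
#' @param contamination fraction of short-insert RF contaminant pairs.
#' @param seed integer seed.
#' @return tibble: `id`, `qf`, `qr`, `true_start` (0-based fragment
#'   start), `true_insert`, `contaminant`.
#' @export
simulate_illumina_pairs <- function(genome, read_len = 100L,
                                    insert_mean = 3000, insert_sd = 300,
                                    n_pairs = 10000L, error_rate = 0,
                                    contamination = 0, seed = NULL) {
  if (is.list(genome)) genome <- genome$sequence
  L <- nchar(genome)
  run <- function() {
    contam <- runif(n_pairs) < contamination
    ins <- ifelse(contam,
                  round(rnorm(n_pairs, 300, 50)),
                  round(rnorm(n_pairs, insert_mean, insert_sd)))
    ins <- pmax(2L * read_len, pmin(as.integer(ins), L))
    u <- vapply(ins, function(i) sample.int(L - i + 1L, 1L) - 1L, integer(1))
    left <- substring(genome, u + 1L, u + read_len)
    right <- substring(genome, u + ins - read_len + 1L, u + ins)
    qf <- ifelse(contam, revcomp(left), left)
    qr <- ifelse(contam, right, revcomp(right))
    tibble(id = sprintf("sim_pair_%06d", seq_len(n_pairs)),
           qf = .add_substitutions(qf, error_rate),
           qr = .add_substitutions(qr, error_rate),
           true_start = u, true_insert = ins, contaminant = contam)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# long-read error profiles: proportions of deletion/substitution/insertion
.error_profiles <- list(
  ont = c(del = 0.60, sub = 0.25, ins = 0.15),
  pacbio = c(del = 0.15, sub = 0.60, ins = 0.25)
)

.corrupt_long_read <- function(s, rate, profile) {
  if (rate <= 0) return(s)
  p <- .error_profiles[[profile]]
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(ch)
  err <- which(runif(n) < rate)
  if (length(err) == 0) return(s)
  type <- sample(names(p), length(err), replace = TRUE, prob = p)
  bases <- c("A", "C", "G", "T")
  subs <- err[type == "sub"]
  if (length(subs) > 0) {
    cur <- match(ch[subs], bases)
    ch[subs] <- bases[((cur - 1L + sample.int(3L, length(subs), replace = TRUE)) %% 4L) + 1L]
  }
  keep <- rep(TRUE, n)
  keep[err[type == "del"]] <- FALSE
  extra <- rep("", n)
  insat <- err[type == "ins"]
  if (length(insat) > 0) extra[insat] <- sample(bases, length(insat), replace = TRUE)
  paste(paste0(ifelse(keep, ch, ""), extra), collapse = "")
}

#' Simulate long reads with technology-flavoured errors
#'
#' Read lengths are normal (truncated to at least 2 k-mers' worth of
#' sequence and at most the genome); reads are drawn from both strands.
#' Errors are applied per base at `error_rate` and split by profile:
#' ONT-like 60\% deletion / 25\% substitution / 15\% insertion,
#' PacBio-like 60\% substitution / 25\% insertion / 15\% deletion.
#' Deletion-dominant errors shrink read coordinates relative to genomic
#' span, which is why synthetic mate-pairs from ONT-like reads show
#' observed inserts above the nominal distance.
#'
#' @param genome genome string (or [simulate_genome()] output).
#' @param n_reads number of reads.
#' @param mean_len,len_sd read-length distribution, bases.
#' @param error_rate total per-base error probability.
#' @param profile `"ont"` or `"pacbio"`.
#' @param both_strands draw reads from both strands.
#' @param seed integer seed.
#' @return tibble: `id`, `sequence`, `true_start` (0-based genomic start),
#'   `true_end` (exclusive), `strand`, `template_len`.
#' @export
simulate_long_reads <- function(genome, n_reads = 200L, mean_len = 10000,
                                len_sd = 2000, error_rate = 0.15,
                                profile = c("ont", "pacbio"),
                                both_strands = TRUE, seed = NULL) {
  profile <- match.arg(profile)
  if (is.list(genome)) genome <- genome$sequence
  L <- nchar(genome)
  run <- function() {
    len <- pmax(200L, pmin(as.integer(round(rnorm(n_reads, mean_len, len_sd))), L))
    u <- vapply(len, function(l) sample.int(L - l + 1L, 1L) - 1L, integer(1))
    strand <- if (both_strands) sample(c("+", "-"), n_reads, replace = TRUE)
              else rep("+", n_reads)
    raw <- substring(genome, u + 1L, u + len)
    raw[strand == "-"] <- revcomp(raw[strand == "-"])
    sq <- vapply(raw, .corrupt_long_read, character(1), rate = error_rate,
                 profile = profile, USE.NAMES = FALSE)
    tibble(id = sprintf("sim_long_%05d", seq_len(n_reads)),
           sequence = sq, true_start = u, true_end = u + len,
           strand = strand, template_len = len)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Scaffolds from a true layout, and controlled perturbations
#'
#' `layout_to_scaffolds()` turns a truth layout into the single perfect
#' scaffold per reference (truth order, truth orientations, true gaps).
#' `perturb_scaffolds()` then plants specific join errors for evaluation
#' tests: flipping a contig's orientation, swapping two contigs'
#' positions, or adding to a claimed gap.
#'
#' @param layout truth layout tibble (`reference`, `contig`, `start`,
#'   `end`, `strand`).
#' @return scaffold tibble (`scaffold`, `position`, `contig`,
#'   `orientation`, `gap_after`).
#' @export
layout_to_scaffolds <- function(layout) {
  layout |>
    dplyr::group_by(.data$reference) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::mutate(scaffold = paste0("scaffold_", dplyr::cur_group_id()),
                  position = dplyr::row_number(),
                  orientation = .data$strand,
                  gap_after = dplyr::lead(.data$start) - .data$end - 1L) |>
    dplyr::ungroup() |>
    dplyr::select("scaffold", "position", "contig", "orientation", "gap_after")
}

#' @rdname layout_to_scaffolds
#' @param scaffolds scaffold tibble to perturb.
#' @param flip contig names whose orientation is inverted.
#' @param swap length-2 character vector: two contigs exchanging positions.
#' @param gap_add named numeric: amount added to `gap_after` of the named
#'   contigs.
#' @export
perturb_scaffolds <- function(scaffolds, flip = NULL, swap = NULL,
                              gap_add = NULL) {
  out <- scaffolds
  if (!is.null(flip)) {
    i <- out$contig %in% flip
    out$orientation[i] <- .flip_strand(out$orientation[i])
  }
  if (!is.null(swap)) {
    stopifnot(length(swap) == 2)
    i <- match(swap, out$contig)
    stopifnot(!anyNA(i))
    out[i, c("contig", "orientation")] <- out[rev(i), c("contig", "orientation")]
  }
  if (!is.null(gap_add)) {
    i <- match(names(gap_add), out$contig)
    out$gap_after[i] <- out$gap_after[i] + unname(gap_add)
  }
  out
}

#' Generate a complete simulated dataset
#'
#' Runs the whole generator under one seed: genome with planted repeats,
#' fragmentation with layout, Illumina-like pairs and long reads.
#'
#' @param config a [sim_config()].
#' @return list: `genome` (list from [simulate_genome()]), `contigs`,
#'   `layout`, `pairs`, `long_reads`, `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  gen <- simulate_genome(config$genome_length, config$repeats,
                         seed = config$seed)
  frag <- fragment_genome(gen$sequence, n_contigs = config$n_contigs)
  ill <- config$illumina
  pairs <- simulate_illumina_pairs(gen$sequence, read_len = ill$read_len,
                                   insert_mean = ill$insert_mean,
                                   insert_sd = ill$insert_sd,
                                   n_pairs = ill$n_pairs,
                                   error_rate = ill$error_rate,
                                   contamination = ill$contamination,
                                   seed = config$seed + 1L)
  lr <- config$longread
  long_reads <- simulate_long_reads(gen$sequence, n_reads = lr$n_reads,
                                    mean_len = lr$mean_len,
                                    len_sd = lr$len_sd,
                                    error_rate = lr$error_rate,
                                    profile = lr$profile,
                                    seed = config$seed + 2L)
  list(genome = gen, contigs = frag$contigs, layout = frag$layout,
       pairs = pairs, long_reads = long_reads, config = config)
}
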
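#' Construct library parameters
#'
#' Holds the insert-size model used by pair rescue and scaffold-graph gap
#' estimation: mean and standard deviation of the outer insert, the pair
#' orientation, and bookkeeping about how the estimate was obtained.
#'
#' @param mean_insert mean outer insert size, bases.
#' @param sd_insert standard deviation, bases.
#' @param orientation one of `"FR"`, `"RF"`, `"FF"`, `"RR"`.
#' @param n_used number of observations behind the estimate.
#' @param outlier_fraction share of observations trimmed or flagged.
#' @param inserts optional integer vector of the observed inserts (kept
#'   for plotting/QC).
#' @return object of class `library_params`.
#' @export
library_params <- function(mean_insert, sd_insert, orientation = "FR",
                           n_used = NA_integer_, outlier_fraction = NA_real_,
                           inserts = NULL) {
  stopifnot(mean_insert > 0, sd_insert >= 0,
            orientation %in% c("FR", "RF", "FF", "RR"))
  structure(list(mean_insert = mean_insert, sd_insert = sd_insert,
                 orientation = orientation, n_used = n_used,
                 outlier_fraction = outlier_fraction, inserts = inserts),
            class = "library_params")
}

#' @export
print.library_params <- function(x, ...) {
  cat(sprintf("<library_params> mean=%.1f sd=%.1f orientation=%s n=%s outliers=%s\n",
              x$mean_insert, x$sd_insert, x$orientation,
              format(x$n_used), format(x$outlier_fraction, digits = 3)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.library_params <- function(x, ...) {
  tibble(mean_insert = x$mean_insert, sd_insert = x$sd_insert,
         orientation = x$orientation, n_used = x$n_used,
         outlier_fraction = x$outlier_fraction)
}

#' @export
glance.library_params <- function(x, ...) tidy(x)

# sd of a standard normal truncated to its central (1 - 2 trim) mass; the
# raw sd of the trimmed sample underestimates the library sigma by this
# factor (~0.662 at trim = 0.1), so we divide it out to keep the estimate
# consistent for the Gaussian sd that the mu +/- 3 sd rescue window needs
.trunc_sd_factor <- function(trim) {
  if (trim <= 0) return(1)
  b <- stats::qnorm(1 - trim)
  sqrt(1 - 2 * b * stats::dnorm(b) / (1 - 2 * trim))
}

# shared trimming/estimation step: sort inserts, drop floor(0.1 n) from each
# tail, mean/sd on the remainder (sd rescaled to target the untrimmed sigma)
.trimmed_estimate <- function(inserts, trim = 0.1) {
  n <- length(inserts)
  drop <- floor(trim * n)
  s <- sort(inserts)
  kept <- if (drop > 0) s[(drop + 1):(n - drop)] else s
  raw_sd <- if (length(kept) > 1) sd(kept) else 0
  list(mean = mean(kept), sd = raw_sd / .trunc_sd_factor(2 * drop / (2 * n)),
       n_used = length(kept), outlier_fraction = 2 * drop / n)
}

.majority_orientation <- function(orientations) {
  tab <- table(factor(orientations, levels = c("FR", "RR", "FF", "RF")))
  names(tab)[which.max(tab)]  # ties break in FR, RR, FF, RF order
}

#' Estimate library parameters from paired short reads
#'
#' Maps a subsample of pairs (by default the first 100,000) with a report
#' threshold of 8 and rescue disabled, keeps the pairs whose two reads land
#' on one contig, sorts the observed outer inserts and removes 10\% from
#' each tail before computing mean and standard deviation. Orientation is
#' decided by majority over the four possibilities (FR, RR, FF, RF) across
#' all within-contig pairs, so even heavily contaminated libraries resolve
#' to their dominant orientation.
#'
#' @param pairs tibble with `qf`, `qr` (and optionally `id`).
#' @param index a `kmer_index`.
#' @param n_sample number of pairs to examine.
#' @param min_score report threshold used during estimation.
#' @param hit_capacity hits per read.
#' @param min_usable minimum within-contig pairs required (error below).
#' @param trim fraction removed from each tail.
#' @return a [library_params()] with the observed inserts attached.
#' @export
estimate_library_illumina <- function(pairs, index, n_sample = 100000L,
                                      min_score = 8L, hit_capacity = 10L,
                                      min_usable = 50L, trim = 0.1) {
  pairs <- head(pairs, n_sample)
  params <- mapper_params(hit_capacity = hit_capacity,
                          min_report_score = min_score, lib = NULL)
  pl <- map_read_pairs(pairs, index, params, keep_sequences = FALSE)
  within <- pl[pl$placed & !is.na(pl$observed_insert), , drop = FALSE]
  if (nrow(within) < min_usable) {
    stop("only ", nrow(within), " pairs mapped within contigs (need ",
         min_usable, "); supply a larger sample")
  }
  est <- .trimmed_estimate(within$observed_insert, trim)
  library_params(est$mean, est$sd,
                 orientation = .majority_orientation(within$orientation),
                 n_used = est$n_used, outlier_fraction = est$outlier_fraction,
                 inserts = within$observed_insert)
}

#' Estimate synthetic library parameters from long reads
#'
#' Uses the first `n_reads` long reads (1,000 by default), extracts and
#' maps the synthetic pairs for every requested insert size without
#' rescue, and applies the same 10\% two-tail trim per library. The
#' orientation is fixed to FR without estimation, since synthetic pairs
#' are created in forward-reverse orientation by construction.
#'
#' @param long_reads tibble with `id`, `sequence`.
#' @param index a `kmer_index`.
#' @param spec a [synthetic_spec()].
#' @param n_reads number of long reads to use.
#' @param min_usable minimum within-contig pairs per library.
#' @param trim fraction removed from each tail.
#' @return named list of [library_params()], keyed by insert size.
#' @export
estimate_library_synthetic <- function(long_reads, index, spec,
                                       n_reads = 1000L, min_usable = 50L,
                                       trim = 0.1) {
  long_reads <- head(long_reads, n_reads)
  pl <- map_long_read_pairs(long_reads, index, spec, libs = NULL)
  out <- list()
  for (D in spec$insert_sizes) {
    within <- pl[pl$placed & pl$library_tag == D & !is.na(pl$observed_insert), ,
                 drop = FALSE]
    if (nrow(within) < min_usable) {
      stop("library D=", D, ": only ", nrow(within),
           " pairs mapped within contigs (need ", min_usable,
           "); supply more long reads")
    }
    est <- .trimmed_estimate(within$observed_insert, trim)
    out[[as.character(D)]] <- library_params(
      est$mean, est$sd, orientation = "FR", n_used = est$n_used,
      outlier_fraction = est$outlier_fraction,
      inserts = within$observed_insert)
  }
  out
}

#' QC summary of observed insert-size distributions
#'
#' Summarises within-contig placements per library: trimmed mean and sd,
#' and the fraction of observations falling outside mean +/- 3 sd. A
#' library is flagged low quality when that outlier fraction exceeds 30\%
#' or the standard deviation exceeds 30\% of the mean — both signs that
#' its linking information should not be trusted for scaffolding.
#'
#' @param placements placement tibble; a `library_tag` column groups
#'   libraries (a single untagged library is summarised as tag `NA`).
#' @param trim trim fraction used for the location/scale estimates.
#' @param max_outlier_fraction,max_sd_fraction flagging thresholds.
#' @return tibble with one row per library: `library_tag`, `n`,
#'   `mean_insert`, `sd_insert`, `outlier_fraction`, `flagged`.
#' @export
insert_qc <- function(placements, trim = 0.1, max_outlier_fraction = 0.30,
                      max_sd_fraction = 0.30) {
  within <- placements[placements$placed & !is.na(placements$observed_insert), ,
                       drop = FALSE]
  if (nrow(within) == 0) stop("no within-contig placements to summarise")
  if (!"library_tag" %in% names(within)) within$library_tag <- NA_integer_
  within |>
    dplyr::group_by(.data$library_tag) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_insert = .trimmed_estimate(.data$observed_insert, trim)$mean,
      sd_insert = .trimmed_estimate(.data$observed_insert, trim)$sd,
      outlier_fraction = mean(
        .data$observed_insert < mean_insert - 3 * sd_insert |
        .data$observed_insert > mean_insert + 3 * sd_insert),
      .groups = "drop") |>
    dplyr::mutate(flagged = .data$outlier_fraction > max_outlier_fraction |
                    .data$sd_insert > max_sd_fraction * .data$mean_insert)
}

#' Histogram of observed insert sizes for a library
#'
#' @param object a [library_params()] carrying observed inserts.
#' @param binwidth histogram bin width (default: sd/4).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.library_params <- function(object, binwidth = NULL, ...) {
  if (is.null(object$inserts)) stop("no observed inserts stored in this object")
  if (is.null(binwidth)) binwidth <- max(1, object$sd_insert / 4)
  df <- tibble(insert = object$inserts)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$insert)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "steelblue",
                            colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$mean_insert, linetype = 2) +
    ggplot2::labs(x = "observed insert size (bp)", y = "pairs",
                  title = sprintf("insert distribution: mean %.0f, sd %.0f (%s)",
                                  object$mean_insert, object$sd_insert,
                                  object$orientation)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
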
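#' Bin-distribution statistics (minimizer analysis mode)
#'
#' Summarizes the outcome of a binning pass and computes the per-ordering
#' comparison metrics: number of bins, mean/max/stddev of bin sizes, the
#' max/mean ratio, the average super-mer length in k-mers, and the share of
#' k-mer mass held by the largest 0.5% of bins (the primary evenness metric —
#' the smaller, the better balanced the binning). Bin size is the total
#' number of k-mers in the bin prior to counting distinct items, i.e. the sum
#' of (L - (k-1)) over the bin's super-mers.
#'
#' @name binstats
NULL

#' Per-bin summary table
#'
#' One row per nonempty bin: its number of super-mers, distinct k-mers and
#' total k-mers. Totals come from super-mer lengths (`L - (k-1)` k-mers per
#' super-mer of length L); distinct counts from exact per-bin counting.
#'
#' @param supermers A super-mer tibble from [split_supermers()] (or a nested
#'   bin tibble from [bin_supermers()]).
#' @return A `bin_summary` tibble: `minimizer`, `n_supermers`,
#'   `n_distinct_kmers`, `n_total_kmers`, sorted by minimizer, with
#'   attribute `k`.
#' @param k k-mer length.
#' @export
summarize_bins <- function(supermers, k) {
  if ("supermers" %in% names(supermers)) {
    supermers <- tidyr::unnest(supermers, "supermers")
  }
  if (nrow(supermers) == 0L) {
    out <- tibble::tibble(minimizer = character(), n_supermers = integer(),
                          n_distinct_kmers = integer(),
                          n_total_kmers = integer())
  } else {
    sizes <- supermers |>
      dplyr::group_by(.data$minimizer) |>
      dplyr::summarise(
        n_supermers = dplyr::n(),
        n_total_kmers = sum(.data$length - (k - 1L)),
        .groups = "drop"
      )
    nwin <- nchar(supermers$supermer) - k + 1L
    kmer_rows <- tibble::tibble(
      minimizer = rep.int(supermers$minimizer, nwin),
      kmer = segment_kmers(supermers$supermer, k)
    )
    distinct <- kmer_rows |>
      dplyr::distinct() |>
      dplyr::count(.data$minimizer, name = "n_distinct_kmers")
    out <- sizes |>
      dplyr::left_join(distinct, by = "minimizer") |>
      dplyr::select("minimizer", "n_supermers", "n_distinct_kmers",
                    "n_total_kmers") |>
      dplyr::arrange(.data$minimizer)
  }
  attr(out, "k") <- as.integer(k)
  class(out) <- c("bin_summary", class(out))
  out
}

#' Mass share of the largest bins
#'
#' Sorts nonempty bins by total k-mers (descending; ties broken by minimizer
#' for determinism), takes the `ceiling(pct/100 * n_bins)` largest, and
#' returns the percentage of all k-mer mass they hold.
#'
#' @param summaries A `bin_summary` tibble.
#' @param pct Bin percentage in (0, 100); the headline metric uses 0.5.
#' @return A single percentage in `[0, 100]`.
#' @export
top_fraction <- function(summaries, pct = 0.5) {
  if (pct <= 0 || pct >= 100) stop("pct must be in (0, 100)")
  stopifnot(nrow(summaries) >= 1L)
  sizes <- summaries |>
    dplyr::arrange(dplyr::desc(.data$n_total_kmers), .data$minimizer) |>
    dplyr::pull("n_total_kmers")
  n_top <- ceiling(pct / 100 * length(sizes))
  100 * sum(sizes[seq_len(n_top)]) / sum(sizes)
}

#' Comparison metrics for one ordering
#'
#' @param summaries A `bin_summary` tibble from one binning pass.
#' @param top_pct Bin percentage for the mass-share column (default 0.5).
#' @details The standard deviation is the population standard deviation
#'   (divide by N), reading the metrics as descriptive statistics of the
#'   realized bin-size distribution. The average super-mer length is measured
#'   in k-mers: total k-mers divided by total super-mers.
#' @return A one-row `ordering_report` tibble: `n_bins`, `mean_bin`,
#'   `max_bin`, `max_mean_ratio`, `sd_bin`, `avg_supermer_kmers`,
#'   `top_fraction_pct`.
#' @export
ordering_report <- function(summaries, top_pct = 0.5) {
  if (nrow(summaries) == 0L) stop("no nonempty bins to report on")
  sizes <- summaries$n_total_kmers
  mean_bin <- mean(sizes)
  out <- tibble::tibble(
    n_bins = nrow(summaries),
    mean_bin = mean_bin,
    max_bin = max(sizes),
    max_mean_ratio = max(sizes) / mean_bin,
    sd_bin = sqrt(mean((sizes - mean_bin)^2)),
    avg_supermer_kmers = sum(sizes) / sum(summaries$n_supermers),
    top_fraction_pct = top_fraction(summaries, top_pct)
  )
  class(out) <- c("ordering_report", class(out))
  out
}

#' Bin-size sample for density plots
#'
#' @param summaries A `bin_summary` tibble.
#' @return A tibble `size`, `minimizer`, one row per bin, ordered by size
#'   then minimizer — a raw sample suitable for kernel-density plotting.
#' @export
density_points <- function(summaries) {
  stopifnot(nrow(summaries) >= 1L)
  summaries |>
    dplyr::transmute(size = .data$n_total_kmers,
                     minimizer = .data$minimizer) |>
    dplyr::arrange(.data$size, .data$minimizer)
}

#' Density plot of bin sizes
#'
#' @param object A `bin_summary` tibble.
#' @param ... Unused.
#' @return A ggplot: kernel density of log10 bin size (total k-mers).
#' @export
autoplot.bin_summary <- function(object, ...) {
  pts <- density_points(object)
  ggplot2::ggplot(pts, ggplot2::aes(x = log10(.data$size))) +
    ggplot2::geom_density(fill = "steelblue", alpha = 0.4) +
    ggplot2::labs(x = "log10 bin size (total k-mers)", y = "density",
                  title = "k-mer bin size distribution")
}
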
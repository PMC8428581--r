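#' End-to-end runs: configuration, counting mode, analysis mode
#'
#' The pipeline mirrors three stages: *sampling* (optional — estimate m-mer
#' frequencies from a fraction of reads when a frequency ordering is
#' requested), *hashing* (split reads into super-mers under the configured
#' ordering and group them by minimizer) and *processing* (count k-mers per
#' bin, or summarize bin contents in minimizer-analysis mode). All
#' randomness — read sampling, random XOR constants, toy set generation —
#' flows from the single configured seed.
#'
#' @name pipeline
NULL

#' Build a run configuration
#'
#' @param inputs Character vector of FASTA/FASTQ paths.
#' @param k k-mer length.
#' @param m Minimizer length, `1 <= m <= k`.
#' @param ordering One of `lex`, `signature`, `random`, `freq`, `ulex`,
#'   `urand`, `ufreq`.
#' @param sample_fraction Read-sampling fraction for frequency orderings.
#' @param seed Integer seed for all randomized stages.
#' @param uhs Universal hitting set: a file path, a `universal_set` object,
#'   or `"anchored"` to construct [uhs_anchored()] at (m, k). Required for
#'   `ulex`/`urand`/`ufreq`.
#' @param output_prefix Path prefix for output files.
#' @param min_count Minimum multiplicity kept in the counts output (an
#'   output filter only; totals and histograms are computed before it).
#' @return A `run_config` list.
#' @export
run_config <- function(inputs, k, m, ordering = "lex",
                       sample_fraction = 0.01, seed = 1L, uhs = NULL,
                       output_prefix = tempfile("kmerbin_"), min_count = 1L) {
  ordering <- match.arg(ordering,
                        c("lex", "signature", "random", "freq",
                          "ulex", "urand", "ufreq"))
  if (m < 1L || k < m) stop("need k >= m >= 1")
  if (ordering %in% c("ulex", "urand", "ufreq") && is.null(uhs)) {
    stop("ordering '", ordering, "' requires a universal hitting set ",
         "(path, universal_set, or \"anchored\")")
  }
  structure(
    list(inputs = inputs, k = as.integer(k), m = as.integer(m),
         ordering = ordering, sample_fraction = sample_fraction,
         seed = as.integer(seed), uhs = uhs,
         output_prefix = output_prefix, min_count = as.integer(min_count)),
    class = "run_config"
  )
}

.resolve_uhs <- function(config) {
  uhs <- config$uhs
  if (is.null(uhs)) return(NULL)
  if (inherits(uhs, "universal_set")) return(uhs)
  if (identical(uhs, "anchored")) return(uhs_anchored(config$m, config$k))
  read_uhs(uhs, config$m, config$k)
}

.stage <- function(label, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- force(expr)
  message(sprintf("[%s] %.2fs", label, proc.time()[["elapsed"]] - t0))
  res
}

# shared sampling + hashing front end of both modes
.run_hashing <- function(config) {
  reads <- .stage("read", read_sequences(config$inputs))
  uhs <- .resolve_uhs(config)
  ordering <- .stage("sample", build_ordering(
    config$ordering, config$m, reads = reads, uhs = uhs,
    sample_fraction = config$sample_fraction, seed = config$seed))
  supermers <- .stage("hash", split_supermers(reads, config$k, config$m,
                                              ordering))
  list(reads = reads, ordering = ordering, supermers = supermers)
}

#' Run k-mer counting mode
#'
#' Writes `<prefix>_counts.tsv` (one row per distinct k-mer passing
#' `min_count`, lexicographic order) and `<prefix>_histogram.tsv`, and logs
#' per-stage timings plus totals.
#'
#' @param config A `run_config`.
#' @return Invisibly, a list with the counts table, histogram, output paths
#'   and totals (`total_kmers`, `distinct_kmers`, `n_bins`).
#' @export
run_count <- function(config) {
  stopifnot(inherits(config, "run_config"))
  h <- .run_hashing(config)
  counts <- .stage("process", count_all(h$supermers, config$k))
  hist <- count_histogram(counts)
  out_counts <- counts[counts$count >= config$min_count, , drop = FALSE]
  paths <- list(
    counts = paste0(config$output_prefix, "_counts.tsv"),
    histogram = paste0(config$output_prefix, "_histogram.tsv")
  )
  write_counts_tsv(out_counts, paths$counts)
  write_histogram_tsv(hist, paths$histogram)
  totals <- list(total_kmers = sum(counts$count),
                 distinct_kmers = nrow(counts),
                 n_bins = dplyr::n_distinct(h$supermers$minimizer))
  message(sprintf("total k-mers: %d | distinct: %d | bins: %d",
                  totals$total_kmers, totals$distinct_kmers, totals$n_bins))
  invisible(c(list(counts = counts, histogram = hist, paths = paths), totals))
}

#' Run minimizer-analysis mode
#'
#' Writes `<prefix>_bins.tsv` (per-bin super-mers / distinct / total k-mers),
#' `<prefix>_report.tsv` (the per-ordering comparison metrics) and
#' `<prefix>_density.tsv` (the raw bin-size sample).
#'
#' @param config A `run_config`.
#' @return Invisibly, a list with the bin summary, the report and the paths.
#' @export
run_stats <- function(config) {
  stopifnot(inherits(config, "run_config"))
  h <- .run_hashing(config)
  summaries <- .stage("process", summarize_bins(h$supermers, config$k))
  report <- ordering_report(summaries)
  paths <- list(
    bins = paste0(config$output_prefix, "_bins.tsv"),
    report = paste0(config$output_prefix, "_report.tsv"),
    density = paste0(config$output_prefix, "_density.tsv")
  )
  write_binstats_tsv(summaries, paths$bins)
  write_report_tsv(report, paths$report)
  write_density_tsv(density_points(summaries), paths$density)
  message(sprintf("bins: %d | mean size: %.2f | top 0.5%%: %.2f%%",
                  report$n_bins, report$mean_bin, report$top_fraction_pct))
  invisible(list(summaries = summaries, report = report, paths = paths))
}
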
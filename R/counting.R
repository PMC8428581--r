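#' Per-bin k-mer counting (the processing stage)
#'
#' Inside each bin, super-mers are broken back into individual k-mers and
#' tallied exactly. Because every k-mer carries a unique minimizer, it can
#' surface in exactly one bin, so the global counts table is the disjoint
#' union of per-bin tables and no cross-bin merging is ever needed. Counting
#' is purely functional: results do not depend on the order bins are
#' processed in, nor on which ordering produced the binning.
#'
#' Reverse complements are deliberately not unified: counting input "ACGT"
#' at k = 4 yields the key ACGT only.
#'
#' @name counting
NULL

.tally_kmers <- function(kmers) {
  if (length(kmers) == 0L) {
    return(tibble::tibble(kmer = character(), count = integer()))
  }
  tab <- table(kmers)
  out <- tibble::tibble(kmer = names(tab), count = as.integer(tab))
  # byte-wise (C locale) sort for reproducible output
  out[order(out$kmer, method = "radix"), ]
}

#' Count the k-mers of one bin
#'
#' @param bin A super-mer tibble (all rows sharing one minimizer), or a
#'   character vector of super-mer strings.
#' @param k k-mer length.
#' @return A tibble `kmer`, `count` sorted lexicographically; exact
#'   multiplicities, no zero counts.
#' @examples
#' count_bin("ACGTACGT", k = 4)
#' @export
count_bin <- function(bin, k) {
  strings <- if (is.data.frame(bin)) bin$supermer else bin
  .tally_kmers(segment_kmers(strings, k))
}

#' Count all k-mers across bins
#'
#' Aggregates per-bin tables into the dataset-wide counts table. A k-mer
#' appearing in more than one bin indicates corrupt input (super-mers not
#' produced by a single binning pass) and is an error.
#'
#' @param bins A nested bin tibble from [bin_supermers()], or a flat
#'   super-mer tibble from [split_supermers()] (grouped internally).
#' @param k k-mer length.
#' @return A `kmer_counts` tibble `kmer`, `count`, sorted lexicographically,
#'   with attribute `k`.
#' @export
count_all <- function(bins, k) {
  if ("supermers" %in% names(bins)) {
    per_bin <- lapply(bins$supermers, count_bin, k = k)
  } else {
    if (nrow(bins) > 0L) {
      stopifnot("minimizer" %in% names(bins))
      per_bin <- bins |>
        dplyr::group_by(.data$minimizer) |>
        dplyr::group_map(~ count_bin(.x, k = k))
    } else {
      per_bin <- list()
    }
  }
  merged <- dplyr::bind_rows(per_bin)
  if (anyDuplicated(merged$kmer)) {
    stop("corrupt input: the same k-mer surfaced from two bins")
  }
  out <- merged[order(merged$kmer, method = "radix"), , drop = FALSE]
  if (nrow(out) == 0L) out <- tibble::tibble(kmer = character(), count = integer())
  attr(out, "k") <- as.integer(k)
  class(out) <- c("kmer_counts", class(out))
  out
}

#' Abundance histogram of a counts table
#'
#' Tabulates, for each multiplicity c, the number of distinct k-mers seen
#' exactly c times. Invariants: `sum(multiplicity * n_kmers)` equals total
#' k-mer mass and `sum(n_kmers)` equals the number of distinct k-mers.
#'
#' @param counts A counts tibble (`kmer`, `count`).
#' @return A tibble `multiplicity`, `n_kmers`, ascending in multiplicity.
#' @export
count_histogram <- function(counts) {
  if (nrow(counts) == 0L) {
    return(tibble::tibble(multiplicity = integer(), n_kmers = integer()))
  }
  counts |>
    dplyr::count(multiplicity = .data$count, name = "n_kmers") |>
    dplyr::arrange(.data$multiplicity)
}
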
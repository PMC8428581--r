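#' Super-mer construction (the hashing stage)
#'
#' Every k-mer window of a clean segment is classified by its minimizer — the
#' m-mer of minimal rank among its k-m+1 positions under the active ordering.
#' Consecutive windows sharing a minimizer merge into one super-mer: a maximal
#' substring whose k-mers all share that minimizer. A segment of length n thus
#' splits into super-mers of lengths L_i with sum(L_i - (k-1)) = n - k + 1,
#' i.e. the super-mers carry exactly the segment's k-mer mass with (k-1)
#' letters of overlap between neighbours.
#'
#' @name supermers
NULL

# Window minima over a rank vector: for each of the (length - w + 1) windows
# of width w, the leftmost position (1-based) achieving the minimum rank.
# Rank ties only occur between occurrences of the same m-mer (ranks are
# injective over distinct m-mers), so "leftmost min" = leftmost occurrence.
.window_argmin <- function(ranks, w) {
  if (w == 1L) return(seq_along(ranks))
  e <- embed(ranks, w)[, w:1, drop = FALSE] # row i = ranks[i .. i+w-1]
  max.col(-e, ties.method = "first")
}

#' Minimizer of a single k-mer
#'
#' @param kmer A k-mer string (or an `EncodedMer`-style tibble row from
#'   [iterate_kmers()], in which case its `kmer` column is used).
#' @param m Minimizer length, `m <= k`.
#' @param ordering A `min_ordering`.
#' @return A one-row tibble: `mmer`, `code`, `position` (0-based, leftmost
#'   occurrence when the same m-mer appears more than once).
#' @examples
#' window_minimizer("ATGGC", 3, ordering_lex(3))
#' @export
window_minimizer <- function(kmer, m, ordering) {
  if (is.data.frame(kmer)) kmer <- kmer$kmer
  stopifnot(is.character(kmer), length(kmer) == 1L)
  k <- nchar(kmer)
  if (k < m) stop("k must be >= m")
  codes <- mer_codes(kmer, m)
  ranks <- mmer_rank(ordering, codes)
  pos <- which.min(ranks)
  tibble::tibble(mmer = decode_mer(codes[pos], m), code = codes[pos],
                 position = pos - 1L)
}

#' Split reads or segments into super-mers
#'
#' @param x Either a read tibble (`read_id`, `sequence`) — sanitized
#'   internally — or a segment tibble (`read_id`, `segment`, `offset`) from
#'   [sanitize_reads()].
#' @param k k-mer length.
#' @param m Minimizer length, `1 <= m <= k`.
#' @param ordering A `min_ordering` with matching m.
#' @return A tibble with one row per super-mer, in read order: `read_id`,
#'   `start` (0-based offset in the original read), `length` (letters, always
#'   `>= k`), `minimizer` (m-mer string), `supermer` (the letters). Segments
#'   shorter than k contribute no rows.
#' @examples
#' reads <- tibble::tibble(read_id = "r1", sequence = "ATGGCATGCA")
#' split_supermers(reads, k = 5, m = 3, ordering_lex(3))
#' @export
split_supermers <- function(x, k, m, ordering) {
  stopifnot(inherits(ordering, "min_ordering"))
  if (m > k) stop("k must be >= m")
  if (m != ordering$m) stop("ordering has m = ", ordering$m, ", expected ", m)
  segs <- if ("sequence" %in% names(x)) sanitize_reads(x) else x
  stopifnot(all(c("read_id", "segment", "offset") %in% names(segs)))
  segs <- segs[nchar(segs$segment) >= k, , drop = FALSE]
  if (nrow(segs) == 0L) {
    return(tibble::tibble(read_id = character(), start = integer(),
                          length = integer(), minimizer = character(),
                          supermer = character()))
  }
  # rank all m-mer codes of all segments in one call (rank functions may
  # carry large lookup tables; batching keeps them amortized)
  codes_by_seg <- lapply(segs$segment, mer_codes, m = m)
  lens <- lengths(codes_by_seg)
  ranks_all <- mmer_rank(ordering, unlist(codes_by_seg, use.names = FALSE))
  ranks_by_seg <- split(ranks_all, rep.int(seq_along(lens), lens))
  w <- k - m + 1L
  out <- vector("list", nrow(segs))
  for (i in seq_len(nrow(segs))) {
    codes <- codes_by_seg[[i]]
    pos <- .window_argmin(ranks_by_seg[[i]], w)
    nwin <- length(pos)
    # minimizer code of each k-window, then run-length merge
    win_min <- codes[seq_len(nwin) + pos - 1L]
    r <- rle(win_min)
    ends <- cumsum(r$lengths)          # last window index of each run
    starts <- ends - r$lengths + 1L    # first window index of each run
    out[[i]] <- tibble::tibble(
      read_id = segs$read_id[i],
      start = segs$offset[i] + starts - 1L,
      length = (ends + k - 1L) - starts + 1L,
      minimizer = decode_mer(r$values, m),
      supermer = stringr::str_sub(segs$segment[i], starts, ends + k - 1L)
    )
  }
  dplyr::bind_rows(out)
}

#' Group super-mers into bins by minimizer
#'
#' Each bin corresponds to one minimizer and holds all super-mers (hence all
#' k-mers) assigned to it; total k-mer mass is preserved.
#'
#' @param supermers A super-mer tibble from [split_supermers()].
#' @return A nested tibble with one row per bin: `minimizer` and `supermers`
#'   (a list-column of per-bin super-mer tibbles), sorted by minimizer.
#' @export
bin_supermers <- function(supermers) {
  if (nrow(supermers) == 0L) {
    return(tibble::tibble(minimizer = character(), supermers = list()))
  }
  out <- supermers |>
    tidyr::nest(supermers = -"minimizer") |>
    dplyr::arrange(.data$minimizer)
  out
}
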
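#' Nucleotide codec: 2-bit encoding and k-mer windows
#'
#' DNA strings over {A,C,G,T} are packed two bits per letter (A=0, C=1, G=2,
#' T=3) with the leftmost letter in the most significant bits, so that
#' lexicographic order of equal-length strings equals numeric order of their
#' codes. Codes are stored as doubles, which are exact integers up to 2^53;
#' [encode_mer()] therefore accepts strings of at most 26 letters. Minimizer
#' lengths (m <= 15) always fit comfortably.
#'
#' @name codec
NULL

.BASES <- c("A", "C", "G", "T")

# letter -> 0..3 lookup indexed by ASCII code; NA for anything else
.BASE_LUT <- local({
  lut <- rep(NA_integer_, 127L)
  lut[utf8ToInt("A")] <- 0L
  lut[utf8ToInt("C")] <- 1L
  lut[utf8ToInt("G")] <- 2L
  lut[utf8ToInt("T")] <- 3L
  lut
})

# integer digit vector (0..3) for one ACGT string; NA digits for other letters
.base_digits <- function(s) {
  .BASE_LUT[utf8ToInt(s)]
}

#' Split a raw sequence into clean ACGT segments
#'
#' Uppercases the input and splits it at every character outside {A,C,G,T}
#' (Ns, IUPAC ambiguity codes, gaps...). k-mers never span a split. Offsets
#' are 0-based positions in the original read.
#'
#' @param raw_sequence Character vector of raw read sequences.
#' @return A tibble with columns `segment` (ACGT-only string) and `offset`
#'   (0-based start of the segment in its source string), plus `input` (index
#'   into `raw_sequence`) when more than one sequence is given.
#' @examples
#' sanitize("ACnnGT")
#' @export
sanitize <- function(raw_sequence) {
  stopifnot(is.character(raw_sequence))
  up <- toupper(raw_sequence)
  loc <- stringr::str_locate_all(up, "[ACGT]+")
  out <- purrr::map2_dfr(up, seq_along(up), function(s, i) {
    m <- loc[[i]]
    if (nrow(m) == 0L) {
      return(tibble::tibble(input = integer(), segment = character(),
                            offset = integer()))
    }
    tibble::tibble(
      input = i,
      segment = stringr::str_sub(s, m[, 1L], m[, 2L]),
      offset = as.integer(m[, 1L] - 1L)
    )
  })
  if (length(raw_sequence) == 1L) out$input <- NULL
  out
}

#' Sanitize a tibble of reads
#'
#' Applies [sanitize()] to each read, keeping read identifiers.
#'
#' @param reads A tibble with columns `read_id` and `sequence` (as returned by
#'   [read_sequences()] or [generate_reads()]).
#' @return A tibble with columns `read_id`, `segment`, `offset`.
#' @export
sanitize_reads <- function(reads) {
  stopifnot(all(c("read_id", "sequence") %in% names(reads)))
  seg <- sanitize(reads$sequence)
  if (nrow(seg) == 0L) {
    return(tibble::tibble(read_id = character(), segment = character(),
                          offset = integer()))
  }
  idx <- if ("input" %in% names(seg)) seg$input else rep(1L, nrow(seg))
  tibble::tibble(
    read_id = reads$read_id[idx],
    segment = seg$segment,
    offset = seg$offset
  )
}

#' Encode ACGT strings as 2-bit integer codes
#'
#' @param s Character vector of non-empty ACGT strings (uppercase), all of
#'   the same length, at most 26 letters (codes stay exact in doubles).
#' @return Numeric vector of codes in `[0, 4^length)`.
#' @examples
#' encode_mer("ACGT") # 27
#' @export
encode_mer <- function(s) {
  stopifnot(is.character(s), length(s) >= 1L)
  n <- nchar(s)
  if (any(n == 0L)) stop("empty string cannot be encoded")
  len <- n[1L]
  if (!all(n == len)) stop("all strings must have equal length")
  if (len > 26L) stop("strings longer than 26 letters cannot be encoded exactly")
  pow <- 4^((len - 1L):0L)
  vapply(s, function(x) {
    d <- .base_digits(x)
    if (anyNA(d)) stop("non-ACGT letter in '", x, "'")
    sum(d * pow)
  }, numeric(1L), USE.NAMES = FALSE)
}

#' Decode 2-bit codes back to ACGT strings
#'
#' @param code Numeric vector of codes.
#' @param length Letter count of the encoded strings.
#' @return Character vector of ACGT strings.
#' @examples
#' decode_mer(27, 4) # "ACGT"
#' @export
decode_mer <- function(code, length) {
  stopifnot(length >= 1L, length <= 26L, all(code >= 0), all(code < 4^length))
  if (base::length(code) == 0L) return(character())
  digits <- matrix(0L, nrow = base::length(code), ncol = length)
  rest <- code
  for (j in length:1L) {
    digits[, j] <- as.integer(rest %% 4)
    rest <- rest %/% 4
  }
  apply(digits, 1L, function(d) paste0(.BASES[d + 1L], collapse = ""))
}

# Rolling 2-bit codes for all m-windows of one ACGT string.
# Returns integer vector of length max(0, nchar(s) - m + 1), window i starting
# at letter i (1-based). Uses a one-pass convolution; exact for m <= 15.
mer_codes <- function(s, m) {
  stopifnot(m >= 1L, m <= 15L)
  d <- .base_digits(s)
  n <- length(d)
  if (n < m) return(integer())
  if (anyNA(d)) stop("non-ACGT letter in segment")
  if (m == 1L) return(d)
  y <- stats::filter(d, 4^(0:(m - 1L)), method = "convolution", sides = 1)
  as.integer(y[m:n])
}

#' Enumerate the k-mer windows of a segment
#'
#' Yields the overlapping length-k windows of an ACGT segment in left-to-right
#' order; a segment shorter than k yields no rows.
#'
#' @param segment One ACGT string (or a single-row slice of a segment tibble).
#' @param k Window length, `k >= 1`.
#' @return A tibble with columns `position` (0-based window start), `kmer`
#'   (string) and `code` (2-bit numeric code when `k <= 26`, otherwise `NA`).
#' @examples
#' iterate_kmers("ACGTA", k = 4)
#' @export
iterate_kmers <- function(segment, k) {
  if (is.data.frame(segment)) segment <- segment$segment
  stopifnot(is.character(segment), length(segment) == 1L)
  if (k < 1L) stop("k must be >= 1")
  n <- nchar(segment)
  if (n < k) {
    return(tibble::tibble(position = integer(), kmer = character(),
                          code = numeric()))
  }
  starts <- seq_len(n - k + 1L)
  kmers <- stringr::str_sub(segment, starts, starts + k - 1L)
  code <- if (k <= 26L) encode_mer(kmers) else rep(NA_real_, length(kmers))
  tibble::tibble(position = starts - 1L, kmer = kmers, code = code)
}

# All k-mer strings of a character vector of segments, concatenated.
# Internal workhorse for counting and oracles.
segment_kmers <- function(segments, k) {
  n <- nchar(segments)
  keep <- n >= k
  if (!any(keep)) return(character())
  segments <- segments[keep]
  n <- n[keep]
  nwin <- n - k + 1L
  idx <- rep.int(seq_along(segments), nwin)
  starts <- sequence(nwin)
  stringr::str_sub(segments[idx], starts, starts + k - 1L)
}
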
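#' Synthetic read generation
#'
#' A seeded generator for test fixtures. Reads are assembled from consecutive
#' blocks of the motif length: each block is either the motif (with
#' probability `motif_rate`) or i.i.d. letters drawn from `base_weights`,
#' then the read is truncated to its length and per-position N noise is
#' applied. A high `motif_rate` with an A/T-rich motif concentrates m-mer
#' frequency mass the way low-complexity repeats do in real sequencing data,
#' which is what makes lexicographic binning uneven; this is the property the
#' fixtures need, not a realistic community or error model.
#'
#' @name synthetic-reads
NULL

#' Specify a synthetic read set
#'
#' @param n_reads Number of reads.
#' @param read_length Maximum read length (letters).
#' @param min_length Minimum read length; lengths are drawn uniformly from
#'   `min_length:read_length` (default: fixed-length reads).
#' @param seed Integer seed; the whole read set is a pure function of the spec.
#' @param motif ACGT string inserted as whole blocks.
#' @param motif_rate Probability that a block is the motif, in `[0, 1]`.
#' @param n_rate Per-position probability of replacing a letter with N.
#' @param base_weights Sampling weights for A, C, G, T background letters.
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(n_reads = 200L, read_length = 150L,
                       min_length = read_length, seed = 1L,
                       motif = "AAAATAAAATAAAATA", motif_rate = 0,
                       n_rate = 0.01,
                       base_weights = c(A = 1, C = 1, G = 1, T = 1)) {
  if (read_length < 1L) stop("read_length must be >= 1")
  stopifnot(min_length >= 1L, min_length <= read_length,
            motif_rate >= 0, motif_rate <= 1, n_rate >= 0, n_rate <= 1,
            length(base_weights) == 4L, all(base_weights >= 0),
            grepl("^[ACGT]+$", motif))
  structure(
    list(n_reads = as.integer(n_reads), read_length = as.integer(read_length),
         min_length = as.integer(min_length), seed = as.integer(seed),
         motif = motif, motif_rate = motif_rate, n_rate = n_rate,
         base_weights = base_weights / sum(base_weights)),
    class = "synth_spec"
  )
}

#' Generate a synthetic read set
#'
#' @param spec A `synth_spec`.
#' @return A tibble `read_id`, `sequence`; identical across runs for the same
#'   spec (including seed).
#' @examples
#' generate_reads(synth_spec(n_reads = 3, read_length = 30, seed = 7))
#' @export
generate_reads <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  withr::with_seed(spec$seed, {
    block_len <- nchar(spec$motif)
    n_blocks <- ceiling(spec$read_length / block_len)
    lens <- if (spec$min_length < spec$read_length) {
      sample(spec$min_length:spec$read_length, spec$n_reads, replace = TRUE)
    } else {
      rep(spec$read_length, spec$n_reads)
    }
    seqs <- vapply(seq_len(spec$n_reads), function(i) {
      blocks <- vapply(seq_len(n_blocks), function(b) {
        if (runif(1) < spec$motif_rate) {
          spec$motif
        } else {
          paste0(sample(.BASES, block_len, replace = TRUE,
                        prob = spec$base_weights), collapse = "")
        }
      }, character(1L))
      s <- substr(paste0(blocks, collapse = ""), 1L, lens[i])
      if (spec$n_rate > 0) {
        ch <- strsplit(s, "", fixed = TRUE)[[1L]]
        ch[runif(length(ch)) < spec$n_rate] <- "N"
        s <- paste0(ch, collapse = "")
      }
      s
    }, character(1L))
    tibble::tibble(
      read_id = sprintf("synth_%0*d", nchar(spec$n_reads), seq_len(spec$n_reads)),
      sequence = seqs
    )
  })
}
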
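#' Minimizer orderings
#'
#' A minimizer ordering is a strict total order over all 4^m m-mers: the
#' minimizer of a k-mer window is its m-mer of minimal rank. Orderings are
#' represented as objects carrying a pure, vectorized rank function; lower
#' rank means higher priority. Six orderings are provided:
#'
#' * `lex` — plain lexicographic (A < C < G < T), rank = 2-bit code;
#' * `signature` — KMC2-style: m-mers starting with AAA or ACA, or containing
#'   AA anywhere except at the very start, are demoted below all others;
#'   within each class the order is lexicographic;
#' * `random` — rank = code XOR a seeded 2m-bit constant;
#' * `freq` — rare-to-common by sampled occurrence count, ties lexicographic;
#' * `ulex` / `urand` / `ufreq` — any of the above restricted by a universal
#'   k-mer hitting set: non-members are demoted below all members, which
#'   effectively excludes them from ever being chosen in a window the set hits.
#'
#' @name minimizer-orderings
NULL

new_min_ordering <- function(name, m, span, rank_fn, meta = list()) {
  structure(
    list(name = name, m = as.integer(m), span = span, rank_fn = rank_fn,
         meta = meta),
    class = "min_ordering"
  )
}

#' @export
print.min_ordering <- function(x, ...) {
  cat("<min_ordering> ", x$name, " (m = ", x$m, ")\n", sep = "")
  if (!is.null(x$meta$seed)) cat("  seed: ", x$meta$seed, "\n", sep = "")
  if (!is.null(x$meta$uhs_size)) {
    cat("  universal set: ", x$meta$uhs_size, " members (k = ",
        x$meta$uhs_k, ")\n", sep = "")
  }
  invisible(x)
}

#' Rank m-mers under an ordering
#'
#' @param ordering A `min_ordering` object.
#' @param codes Numeric vector of m-mer codes (see [encode_mer()]), or a
#'   character vector of m-mer strings.
#' @return Numeric rank vector; ranks are injective over all 4^m m-mers and
#'   lie in `[0, ordering$span)`.
#' @export
mmer_rank <- function(ordering, codes) {
  stopifnot(inherits(ordering, "min_ordering"))
  if (is.character(codes)) codes <- encode_mer(codes)
  stopifnot(all(codes >= 0), all(codes < 4^ordering$m))
  ordering$rank_fn(codes)
}

.check_m <- function(m, lower = 1L) {
  if (m < lower || m > 15L) {
    stop("m must be between ", lower, " and 15")
  }
  as.integer(m)
}

#' @rdname minimizer-orderings
#' @param m Minimizer length, `1 <= m <= 15`.
#' @return A `min_ordering` object.
#' @examples
#' o <- ordering_lex(3)
#' mmer_rank(o, c("AAA", "TTT"))
#' @export
ordering_lex <- function(m) {
  m <- .check_m(m)
  new_min_ordering("lex", m, span = 4^m, rank_fn = function(codes) {
    as.numeric(codes)
  })
}

# digit matrix (n x m, entries 0..3) for a vector of m-mer codes
.code_digits <- function(codes, m) {
  digits <- matrix(0L, nrow = length(codes), ncol = m)
  rest <- as.numeric(codes)
  for (j in m:1L) {
    digits[, j] <- as.integer(rest %% 4)
    rest <- rest %/% 4
  }
  digits
}

# KMC2 signature demotion rule: starts with AAA, starts with ACA, or has AA
# starting at any 0-based position >= 1.
.signature_disallowed <- function(codes, m) {
  d <- .code_digits(codes, m)
  starts_aaa <- d[, 1L] == 0L & d[, 2L] == 0L & d[, 3L] == 0L
  starts_aca <- d[, 1L] == 0L & d[, 2L] == 1L & d[, 3L] == 0L
  internal_aa <- rep(FALSE, length(codes))
  if (m >= 3L) {
    for (j in 2L:(m - 1L)) {
      internal_aa <- internal_aa | (d[, j] == 0L & d[, j + 1L] == 0L)
    }
  }
  starts_aaa | starts_aca | internal_aa
}

#' @rdname minimizer-orderings
#' @export
ordering_signature <- function(m) {
  if (m < 3L) stop("signature ordering requires m >= 3")
  m <- .check_m(m, lower = 3L)
  span1 <- 4^m
  new_min_ordering("signature", m, span = 2 * span1, rank_fn = function(codes) {
    as.numeric(codes) + .signature_disallowed(codes, m) * span1
  })
}

#' @rdname minimizer-orderings
#' @param seed Integer seed for the XOR constant; the same seed always yields
#'   the same ordering. `NULL` draws a constant from the session RNG.
#' @param xor_const Directly supply the 2m-bit XOR constant (overrides
#'   `seed`); `xor_const = 0` recovers the lexicographic ordering.
#' @export
ordering_random <- function(m, seed = NULL, xor_const = NULL) {
  m <- .check_m(m)
  if (is.null(xor_const)) {
    if (is.null(seed)) {
      xor_const <- sample.int(4^m, 1L) - 1L
    } else {
      xor_const <- withr::with_seed(seed, sample.int(4^m, 1L) - 1L)
    }
  }
  xor_const <- as.integer(xor_const)
  stopifnot(xor_const >= 0L, xor_const < 4^m)
  new_min_ordering("random", m, span = 4^m, rank_fn = function(codes) {
    as.numeric(bitwXor(as.integer(codes), xor_const))
  }, meta = list(seed = seed, xor_const = xor_const))
}

#' Sample m-mer frequencies from reads
#'
#' Each read is independently included with probability `fraction` (seeded);
#' for every included read, every overlapping m-mer occurrence in every
#' clean ACGT segment is counted once. The resulting table drives the
#' frequency-sampled orderings; the default fraction mirrors common practice
#' of sampling 1% of reads, which is cheap yet yields stable orderings.
#'
#' @param reads Tibble with columns `read_id`, `sequence`.
#' @param m Minimizer length.
#' @param fraction Per-read inclusion probability in (0, 1].
#' @param seed Integer seed for the read sample.
#' @return A tibble of class `mmer_freq` with columns `code`, `mmer`, `count`
#'   (only m-mers seen at least once), and attributes `m`, `fraction`, `seed`.
#' @export
sample_frequencies <- function(reads, m, fraction = 0.01, seed = 1L) {
  m <- .check_m(m)
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  keep <- withr::with_seed(seed, runif(nrow(reads)) < fraction)
  segs <- sanitize_reads(reads[keep, , drop = FALSE])
  codes <- unlist(lapply(segs$segment, mer_codes, m = m), use.names = FALSE)
  if (length(codes) == 0L) {
    tab <- tibble::tibble(code = numeric(), mmer = character(),
                          count = integer())
  } else if (m <= 12L) {
    cnt <- tabulate(codes + 1L, nbins = 4^m)
    seen <- which(cnt > 0L)
    tab <- tibble::tibble(code = as.numeric(seen - 1L),
                          mmer = decode_mer(seen - 1L, m),
                          count = cnt[seen])
  } else {
    agg <- table(codes)
    code <- as.numeric(names(agg))
    ord <- order(code)
    tab <- tibble::tibble(code = code[ord], mmer = decode_mer(code[ord], m),
                          count = as.integer(agg)[ord])
  }
  attr(tab, "m") <- m
  attr(tab, "fraction") <- fraction
  attr(tab, "seed") <- seed
  class(tab) <- c("mmer_freq", class(tab))
  tab
}

#' @rdname minimizer-orderings
#' @param freq_table An `mmer_freq` table from [sample_frequencies()], or any
#'   tibble with columns `code` (or `mmer`) and `count` plus an `m` attribute
#'   (pass `m` explicitly otherwise).
#' @details For the frequency ordering, rank is the pair (sampled count,
#'   lexicographic code) in ascending order: rare before common, ties broken
#'   lexicographically, and m-mers never seen in the sample (count 0) rank
#'   before all seen ones.
#' @export
ordering_freq <- function(freq_table, m = attr(freq_table, "m")) {
  if (is.null(m)) stop("minimizer length m not found; pass m explicitly")
  m <- .check_m(m)
  tab <- freq_table
  code <- if ("code" %in% names(tab)) as.numeric(tab$code) else encode_mer(tab$mmer)
  count <- as.numeric(tab$count)
  stopifnot(all(code >= 0), all(code < 4^m), all(count >= 0))
  span1 <- 4^m
  if (m <= 12L) {
    lut <- numeric(4^m)
    lut[code + 1L] <- count
    lookup <- function(codes) lut[as.integer(codes) + 1L]
  } else {
    ord <- order(code)
    code <- code[ord]; count <- count[ord]
    lookup <- function(codes) {
      i <- match(codes, code)
      out <- count[i]
      out[is.na(i)] <- 0
      out
    }
  }
  max_count <- if (length(count)) max(count) else 0
  new_min_ordering("freq", m, span = (max_count + 1) * span1,
    rank_fn = function(codes) {
      lookup(codes) * span1 + as.numeric(codes)
    },
    meta = list(fraction = attr(freq_table, "fraction"),
                seed = attr(freq_table, "seed")))
}

#' @rdname minimizer-orderings
#' @param base A `min_ordering` to restrict.
#' @param uhs A `universal_set` (see [read_uhs()], [generate_uhs()],
#'   [uhs_anchored()]) with the same m as `base`.
#' @details Universal restriction demotes every m-mer outside the hitting set
#'   below every member while preserving the base order within each class.
#'   Because the set hits every k-length sequence, the chosen minimizer of a
#'   k-mer window is always a member, so at most `|uhs|` bins can arise.
#' @export
ordering_universal <- function(base, uhs) {
  stopifnot(inherits(base, "min_ordering"), inherits(uhs, "universal_set"))
  if (uhs$m != base$m) {
    stop("universal set m (", uhs$m, ") does not match ordering m (",
         base$m, ")")
  }
  m <- base$m
  if (m <= 12L) {
    member <- logical(4^m)
    member[uhs$members + 1L] <- TRUE
    is_member <- function(codes) member[as.integer(codes) + 1L]
  } else {
    members <- uhs$members
    is_member <- function(codes) !is.na(match(codes, members))
  }
  span1 <- base$span
  rank_base <- base$rank_fn
  new_min_ordering(paste0("universal_", base$name), m, span = 2 * span1,
    rank_fn = function(codes) {
      rank_base(codes) + (!is_member(codes)) * span1
    },
    meta = c(base$meta, list(uhs_size = length(uhs$members), uhs_k = uhs$k)))
}

#' Build an ordering from a CLI-style token
#'
#' Resolves one of the tokens `lex`, `signature`, `random`, `freq`, `ulex`,
#' `urand`, `ufreq` into a [minimizer-orderings] object, running the sampling
#' stage and/or universal-set restriction where the token requires it.
#'
#' @param token Ordering name (see above).
#' @param m Minimizer length.
#' @param reads Read tibble; required by `freq` and `ufreq` for sampling.
#' @param uhs A `universal_set`; required by `ulex`, `urand`, `ufreq`.
#' @param sample_fraction Read-sampling fraction for frequency orderings.
#' @param seed Seed for sampling and random constants.
#' @return A `min_ordering`.
#' @export
build_ordering <- function(token, m, reads = NULL, uhs = NULL,
                           sample_fraction = 0.01, seed = 1L) {
  token <- match.arg(token,
                     c("lex", "signature", "random", "freq",
                       "ulex", "urand", "ufreq"))
  needs_freq <- token %in% c("freq", "ufreq")
  needs_uhs <- token %in% c("ulex", "urand", "ufreq")
  if (needs_freq && is.null(reads)) {
    stop("ordering '", token, "' needs reads for frequency sampling")
  }
  if (needs_uhs && is.null(uhs)) {
    stop("ordering '", token, "' needs a universal hitting set")
  }
  base <- switch(token,
    lex = ,
    ulex = ordering_lex(m),
    signature = ordering_signature(m),
    random = ,
    urand = ordering_random(m, seed = seed),
    freq = ,
    ufreq = ordering_freq(
      sample_frequencies(reads, m, fraction = sample_fraction, seed = seed))
  )
  if (needs_uhs) ordering_universal(base, uhs) else base
}
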
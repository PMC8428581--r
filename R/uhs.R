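#' Universal k-mer hitting sets
#'
#' A universal hitting set for parameters (m, k) is a set of m-mers such that
#' every possible ACGT string of length k contains at least one member as a
#' substring. Restricting a minimizer ordering to such a set ([ordering_universal()])
#' bounds the number of bins by the set size while guaranteeing every window
#' still has a minimizer. Sets are read from plain-text files (one m-mer per
#' line, the convention used by published set generators such as PASHA),
#' verified exactly, or constructed in-package at small scale for testing.
#'
#' @name universal-sets
NULL

new_universal_set <- function(members, m, k, source) {
  structure(
    list(members = sort(unique(as.numeric(members))), m = as.integer(m),
         k = as.integer(k), source = source),
    class = "universal_set"
  )
}

#' @export
print.universal_set <- function(x, ...) {
  cat("<universal_set> m = ", x$m, ", k = ", x$k, ", ",
      length(x$members), " members (", x$source, ")\n", sep = "")
  invisible(x)
}

#' Load a universal hitting set file
#'
#' Reads a plain-text set file with one uppercase m-mer per line (LF or CRLF;
#' blank lines ignored; duplicate lines collapse to one member).
#'
#' @param path File path.
#' @param m Expected m-mer length; every line must have exactly this length.
#' @param k The window length the set is declared valid for (`k >= m`).
#' @return A `universal_set`.
#' @export
read_uhs <- function(path, m, k) {
  stopifnot(file.exists(path), k >= m)
  m <- .check_m(m)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  keep <- nzchar(lines)
  if (!any(keep)) stop("universal set file is empty: ", path)
  idx <- which(keep)
  mm <- lines[keep]
  bad_len <- nchar(mm) != m
  if (any(bad_len)) {
    i <- which(bad_len)[1L]
    stop("line ", idx[i], ": '", mm[i], "' has length ", nchar(mm[i]),
         ", expected m = ", m)
  }
  bad_chr <- !stringr::str_detect(mm, "^[ACGT]+$")
  if (any(bad_chr)) {
    i <- which(bad_chr)[1L]
    stop("line ", idx[i], ": '", mm[i], "' contains non-ACGT characters")
  }
  new_universal_set(encode_mer(mm), m, k, source = path)
}

#' Write a universal hitting set file
#'
#' @param uhs A `universal_set`.
#' @param path Output path (one m-mer per line).
#' @return `path`, invisibly.
#' @export
write_uhs <- function(uhs, path) {
  stopifnot(inherits(uhs, "universal_set"))
  writeLines(decode_mer(uhs$members, uhs$m), path)
  invisible(path)
}

# de Bruijn walk existence check: a k-string avoiding the set is exactly a
# walk of (k - m + 1) edges in the de Bruijn graph on (m-1)-mers whose edges
# are the NON-member m-mers. Returns NULL if no such walk exists (the set is
# universal), otherwise one witness k-string.
.uhs_counterexample <- function(members, m, k) {
  n_mmers <- 4^m
  if (length(members) == n_mmers) return(NULL)
  comp <- setdiff(0:(n_mmers - 1), members) # complement edges
  n_nodes <- 4^(m - 1)
  pre <- comp %/% 4          # (m-1)-prefix node of each edge
  suf <- comp %% n_nodes     # (m-1)-suffix node of each edge
  steps <- k - m + 1L
  # reach[[t]][v+1]: a walk of t complement edges ends at node v
  reach <- vector("list", steps)
  cur <- logical(n_nodes)
  cur[unique(suf) + 1L] <- TRUE
  reach[[1L]] <- cur
  t <- 1L
  while (t < steps) {
    nxt <- logical(n_nodes)
    ok <- cur[pre + 1L]
    if (!any(ok)) return(NULL)
    nxt[unique(suf[ok]) + 1L] <- TRUE
    t <- t + 1L
    reach[[t]] <- nxt
    cur <- nxt
  }
  if (!any(cur)) return(NULL)
  # backtrack one walk: pick an end node, then repeatedly an edge whose
  # suffix is the current node and whose prefix is reachable in t-1 steps
  v <- which(cur)[1L] - 1L
  edges <- numeric(steps)
  for (t in steps:1L) {
    cand <- which(suf == v & (t == 1L | reach[[max(t - 1L, 1L)]][pre + 1L]))
    e <- comp[cand[1L]]
    edges[t] <- e
    v <- e %/% 4
  }
  first <- decode_mer(edges[1L], m)
  if (steps == 1L) return(first)
  last_letters <- vapply(edges[-1L], function(e) .BASES[(e %% 4) + 1L],
                         character(1L))
  paste0(first, paste0(last_letters, collapse = ""))
}

#' Verify the hitting property of a set
#'
#' Checks that every ACGT string of length k contains at least one set member.
#' `mode = "exhaustive"` is exact over all 4^k strings (allowed for k <= 12);
#' it is computed without enumerating strings, via a dynamic program over
#' walks in the de Bruijn graph of the non-member m-mers (a k-string avoiding
#' the set is precisely a walk of k-m+1 such edges). `mode = "sampled"` tests
#' seeded random k-strings.
#'
#' @param uhs A `universal_set`.
#' @param mode `"exhaustive"` or `"sampled"`.
#' @param n_samples Number of random k-strings for sampled mode.
#' @param seed Seed for sampled mode.
#' @return A list with `ok` (logical) and `witness` (a k-string containing no
#'   member, or `NA` when `ok`).
#' @export
verify_uhs <- function(uhs, mode = c("exhaustive", "sampled"),
                       n_samples = 1000L, seed = 1L) {
  stopifnot(inherits(uhs, "universal_set"))
  mode <- match.arg(mode)
  m <- uhs$m; k <- uhs$k
  if (mode == "exhaustive") {
    if (k > 12L) stop("exhaustive verification supports k <= 12 only")
    w <- .uhs_counterexample(uhs$members, m, k)
    return(list(ok = is.null(w), witness = if (is.null(w)) NA_character_ else w))
  }
  mm_strings <- decode_mer(uhs$members, m)
  hits <- withr::with_seed(seed, {
    strs <- vapply(seq_len(n_samples), function(i) {
      paste0(sample(.BASES, k, replace = TRUE), collapse = "")
    }, character(1L))
    strs
  })
  for (s in hits) {
    codes <- mer_codes(s, m)
    if (!any(codes %in% uhs$members)) {
      return(list(ok = FALSE, witness = s))
    }
  }
  list(ok = TRUE, witness = NA_character_)
}

#' Generate a small universal hitting set by greedy removal
#'
#' Starts from all 4^m m-mers and, in a seeded random order, removes each
#' m-mer whose removal leaves the hitting property intact (re-verified
#' exactly after every attempt). Because removability only shrinks as the set
#' shrinks, one pass yields a locally minimal set: removing any single
#' remaining member breaks the hitting property. This is a testing-scale
#' construction, not a near-optimal generator; published tools solve the
#' (NP-hard) minimization problem at realistic (m, k).
#'
#' @param m Minimizer length, `m <= 6`.
#' @param k Window length, `m <= k <= 12`.
#' @param seed Seed controlling the removal order.
#' @return A verified `universal_set` with `source = "generated"`.
#' @export
generate_uhs <- function(m, k, seed = 1L) {
  if (m > 6L) stop("generate_uhs supports m <= 6")
  if (k > 12L) stop("generate_uhs supports k <= 12")
  stopifnot(k >= m, m >= 1L)
  members <- 0:(4^m - 1)
  order_try <- withr::with_seed(seed, sample(members))
  current <- members
  for (cand in order_try) {
    trial <- current[current != cand]
    if (length(trial) == 0L) next
    if (is.null(.uhs_counterexample(trial, m, k))) {
      current <- trial
    }
  }
  uhs <- new_universal_set(current, m, k, source = "generated")
  stopifnot(verify_uhs(uhs, "exhaustive")$ok)
  uhs
}

#' Closed-form anchored universal hitting set
#'
#' Constructs the set of all m-mers that start with A, together with all
#' m-mers containing no A at all. For any `k >= 2m - 1` this is a universal
#' hitting set: if a k-string has an A at some position `p <= k - m`, the
#' window starting at p begins with A and is a member; otherwise positions
#' `0..k-m` are A-free, and since `m - 1 <= k - m` the window at position 0
#' lies entirely in that A-free prefix, so it contains no A and is a member.
#'
#' This synthetic construction is deliberately simple and far larger than the
#' near-optimal sets produced by dedicated tools (its size is
#' `4^(m-1) + 3^m`), but it is provably correct at any scale and makes the
#' universal orderings usable at realistic (m, k) without external files.
#'
#' @param m Minimizer length, `2 <= m <= 12`.
#' @param k Window length, `k >= 2m - 1`.
#' @return A `universal_set` with `source = "anchored"`.
#' @export
uhs_anchored <- function(m, k) {
  stopifnot(m >= 2L, m <= 12L)
  if (k < 2L * m - 1L) stop("anchored construction requires k >= 2m - 1")
  codes <- 0:(4^m - 1)
  starts_a <- codes < 4^(m - 1)
  no_a <- rep(TRUE, length(codes))
  rest <- codes
  for (j in seq_len(m)) {
    no_a <- no_a & (rest %% 4 != 0)
    rest <- rest %/% 4
  }
  new_universal_set(codes[starts_a | no_a], m, k, source = "anchored")
}
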
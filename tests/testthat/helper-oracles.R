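# Independent brute-force oracles. These deliberately use the dumbest
# possible algorithms (per-window rescans, dictionary tallies, full string
# enumeration) so they share no code path with the implementation.

random_dna <- function(n, len, seed, n_rate = 0) {
  withr::with_seed(seed, {
    vapply(seq_len(n), function(i) {
      ch <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
      if (n_rate > 0) ch[runif(len) < n_rate] <- "N"
      paste0(ch, collapse = "")
    }, character(1))
  })
}

reads_tbl <- function(seqs) {
  tibble::tibble(read_id = paste0("r", seq_along(seqs)), sequence = seqs)
}

# all k-mer substrings of one ACGT string, naively
oracle_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character())
  vapply(1:(n - k + 1), function(i) substr(s, i, i + k - 1), character(1))
}

# dictionary tally over sanitized segments of raw reads
oracle_tally <- function(seqs, k) {
  segs <- unlist(lapply(toupper(seqs), function(s) {
    strsplit(gsub("[^ACGT]+", " ", s), " ", fixed = TRUE)[[1]]
  }))
  segs <- segs[nzchar(segs)]
  kmers <- unlist(lapply(segs, oracle_kmers, k = k))
  if (length(kmers) == 0) {
    return(tibble::tibble(kmer = character(), count = integer()))
  }
  tab <- table(kmers)
  out <- tibble::tibble(kmer = names(tab), count = as.integer(tab))
  out[order(out$kmer, method = "radix"), ]
}

# minimizer of one k-mer by rescanning every m-window
oracle_window_minimizer <- function(kmer, m, ordering) {
  mm <- oracle_kmers(kmer, m)
  r <- vapply(mm, function(x) mmer_rank(ordering, encode_mer(x)), numeric(1))
  i <- unname(which.min(r))
  list(mmer = mm[i], position = i - 1L)
}

# super-mer split of one clean segment via per-window rescan + manual merge
oracle_split <- function(segment, k, m, ordering) {
  n <- nchar(segment)
  if (n < k) {
    return(tibble::tibble(start = integer(), length = integer(),
                          minimizer = character(), supermer = character()))
  }
  wins <- oracle_kmers(segment, k)
  mins <- unname(vapply(wins,
                        function(w) oracle_window_minimizer(w, m, ordering)$mmer,
                        character(1)))
  runs <- rle(mins)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  tibble::tibble(
    start = starts - 1L,
    length = ends + k - 1L - starts + 1L,
    minimizer = runs$values,
    supermer = vapply(seq_along(starts),
                      function(i) substr(segment, starts[i], ends[i] + k - 1L),
                      character(1))
  )
}

# exact m-mer occurrence counts over segments, naively
oracle_mmer_counts <- function(seqs, m) {
  tal <- oracle_tally(seqs, m)
  names(tal) <- c("mmer", "count")
  tal
}

# hitting-set verification by enumerating all 4^k strings (tiny k only)
oracle_verify_uhs <- function(members_strings, m, k) {
  grid <- do.call(expand.grid, rep(list(c("A", "C", "G", "T")), k))
  strs <- do.call(paste0, grid)
  for (s in strs) {
    if (!any(vapply(members_strings, function(mm) grepl(mm, s, fixed = TRUE),
                    logical(1)))) {
      return(list(ok = FALSE, witness = s))
    }
  }
  list(ok = TRUE, witness = NA_character_)
}

# every ordering token over a fixed fixture, for parameterized tests
all_ordering_tokens <- c("lex", "signature", "random", "freq",
                         "ulex", "urand", "ufreq")

make_ordering <- function(token, m, k, reads, seed = 11) {
  uhs <- if (token %in% c("ulex", "urand", "ufreq")) {
    if (m <= 4 && k <= 8) generate_uhs(m, k, seed = seed) else uhs_anchored(m, k)
  }
  build_ordering(token, m, reads = reads, uhs = uhs,
                 sample_fraction = 1, seed = seed)
}
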
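lex3 <- ordering_lex(3)

test_that("window_minimizer picks the smallest m-mer, leftmost on repeats", {
  wm <- window_minimizer("ATGGC", 3, lex3)
  expect_equal(wm$mmer, "ATG")
  expect_equal(wm$position, 0L)
  wm2 <- window_minimizer("AAAAA", 3, lex3)
  expect_equal(wm2$mmer, "AAA")
  expect_equal(wm2$position, 0L)
  expect_error(window_minimizer("AC", 3, lex3), "k must be >= m")
})

test_that("window_minimizer agrees with the naive rescan oracle everywhere", {
  reads <- random_dna(30, 20, seed = 13)
  for (token in c("lex", "signature", "random", "freq")) {
    o <- make_ordering(token, 4, 9, reads_tbl(reads))
    for (s in reads[1:10]) {
      for (kmer in oracle_kmers(s, 9)[c(1, 5, 12)]) {
        got <- window_minimizer(kmer, 4, o)
        want <- oracle_window_minimizer(kmer, 4, o)
        expect_equal(got$mmer, want$mmer)
        expect_equal(got$position, want$position)
      }
    }
  }
})

test_that("the k=5, m=3 worked example splits into the expected super-mers", {
  reads <- reads_tbl("ATGGCATGCA")
  sm <- split_supermers(reads, 5, 3, lex3)
  expect_equal(sm$supermer, c("ATGGC", "TGGCA", "GGCAT", "GCATGCA"))
  expect_equal(sm$minimizer, c("ATG", "GCA", "CAT", "ATG"))
  expect_equal(sm$start, c(0L, 1L, 2L, 3L))
  # conservation: sum(L - (k-1)) = n - k + 1
  expect_equal(sum(sm$length - 4), 10 - 5 + 1)
})

test_that("degenerate segments behave per contract", {
  expect_equal(split_supermers(reads_tbl("ACGTT"), 5, 3, lex3)$supermer, "ACGTT")
  expect_equal(split_supermers(reads_tbl("AAAAAAA"), 5, 3, lex3)$supermer,
               "AAAAAAA")
  expect_equal(nrow(split_supermers(reads_tbl("ACG"), 5, 3, lex3)), 0L)
  expect_error(split_supermers(reads_tbl("ACGTT"), 2, 3, lex3), "k must be >= m")
})

test_that("splitting matches the rescan oracle and preserves k-mer structure", {
  reads <- reads_tbl(random_dna(25, 60, seed = 31, n_rate = 0.02))
  params <- list(c(5, 3), c(8, 4), c(28, 10))
  for (p in params) {
    k <- p[1]; m <- p[2]
    for (token in all_ordering_tokens) {
      o <- make_ordering(token, m, k, reads)
      sm <- split_supermers(reads, k, m, o)
      segs <- sanitize_reads(reads)
      segs <- segs[nchar(segs$segment) >= k, ]
      info <- paste(token, k, m)
      # conservation of k-mer mass against direct window count
      expect_equal(sum(sm$length - (k - 1)),
                   sum(nchar(segs$segment) - k + 1), info = info)
      # multiset of k-mers re-windowed from super-mers == direct enumeration
      expect_equal(sort(kmerbin:::segment_kmers(sm$supermer, k)),
                   sort(kmerbin:::segment_kmers(segs$segment, k)), info = info)
      # oracle equivalence on a handful of segments (positions, boundaries)
      if (token %in% c("lex", "signature")) {
        for (i in 1:4) {
          want <- oracle_split(segs$segment[i], k, m, o)
          got <- split_supermers(segs[i, ], k, m, o)
          expect_equal(got$supermer, want$supermer, info = info)
          expect_equal(got$minimizer, want$minimizer, info = info)
          expect_equal(got$start - segs$offset[i], want$start, info = info)
        }
      }
    }
  }
})

test_that("adjacent super-mers from one segment never share a minimizer", {
  reads <- reads_tbl(random_dna(30, 80, seed = 8))
  for (token in c("lex", "random", "freq")) {
    o <- make_ordering(token, 3, 7, reads)
    sm <- split_supermers(reads, 7, 3, o)
    runs <- sm |>
      dplyr::group_by(read_id) |>
      dplyr::summarise(ok = all(minimizer != dplyr::lag(minimizer),
                                na.rm = TRUE))
    expect_true(all(runs$ok), info = token)
  }
})

test_that("under a universal ordering every bin key is a set member", {
  reads <- reads_tbl(random_dna(20, 50, seed = 77))
  uhs <- generate_uhs(3, 7, seed = 1)
  for (base in list(ordering_lex(3), ordering_random(3, seed = 2))) {
    o <- ordering_universal(base, uhs)
    sm <- split_supermers(reads, 7, 3, o)
    expect_true(all(encode_mer(unique(sm$minimizer)) %in% uhs$members))
  }
})

test_that("binning groups by minimizer and preserves mass", {
  sm <- split_supermers(reads_tbl("ATGGCATGCA"), 5, 3, lex3)
  bins <- bin_supermers(sm)
  expect_equal(bins$minimizer, c("ATG", "CAT", "GCA"))
  expect_equal(nrow(bins$supermers[[which(bins$minimizer == "ATG")]]), 2L)
  expect_equal(sum(vapply(bins$supermers,
                          function(b) sum(b$length - 4), numeric(1))), 6)
  empty <- bin_supermers(sm[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("identical seeds reproduce identical decompositions", {
  reads <- reads_tbl(random_dna(15, 40, seed = 3))
  a <- split_supermers(reads, 8, 4, make_ordering("urand", 4, 8, reads, seed = 5))
  b <- split_supermers(reads, 8, 4, make_ordering("urand", 4, 8, reads, seed = 5))
  expect_equal(a, b)
})
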
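fixture_reads <- reads_tbl(random_dna(40, 60, seed = 5, n_rate = 0.01))

test_that("lexicographic ordering ranks by 2-bit code", {
  o <- ordering_lex(3)
  expect_lt(mmer_rank(o, "AAA"), mmer_rank(o, "AAC"))
  expect_equal(mmer_rank(o, "TTT"), 63)
  expect_equal(sort(mmer_rank(ordering_lex(2), 0:15)), as.numeric(0:15))
  expect_error(ordering_lex(16), "between")
})

test_that("signature ordering demotes AAA/ACA starts and internal AA", {
  o <- ordering_signature(5)
  allowed <- function(s) mmer_rank(o, s) < 4^5
  expect_false(allowed("AAACG")) # starts AAA
  expect_false(allowed("ACATG")) # starts ACA
  expect_false(allowed("CGAAT")) # internal AA
  expect_true(allowed("AATGC"))  # AA only at the start
  expect_true(allowed("CGTAC"))
  # every allowed m-mer ranks before every disallowed one
  r <- mmer_rank(o, 0:(4^5 - 1))
  expect_lt(max(r[r < 4^5]), min(r[r >= 4^5]))
  expect_error(ordering_signature(2), "m >= 3")
})

test_that("random ordering is a seeded bijection; xor constant 0 is lexicographic", {
  o0 <- ordering_random(4, xor_const = 0)
  expect_equal(mmer_rank(o0, 0:255), mmer_rank(ordering_lex(4), 0:255))
  o1 <- ordering_random(4, seed = 7)
  o2 <- ordering_random(4, seed = 7)
  expect_equal(mmer_rank(o1, 0:255), mmer_rank(o2, 0:255))
  expect_equal(sort(mmer_rank(o1, 0:255)), as.numeric(0:255))
  o3 <- ordering_random(4, seed = 8)
  expect_false(identical(o1$meta$xor_const, o3$meta$xor_const))
})

test_that("frequency sampling counts every m-mer occurrence in sampled reads", {
  f <- sample_frequencies(reads_tbl("ACGT"), 2, fraction = 1, seed = 1)
  expect_equal(f$mmer, c("AC", "CG", "GT"))
  expect_equal(f$count, c(1L, 1L, 1L))
  f2 <- sample_frequencies(reads_tbl("AAAA"), 2, fraction = 1, seed = 1)
  expect_equal(f2$mmer, "AA")
  expect_equal(f2$count, 3L)
  expect_error(sample_frequencies(fixture_reads, 2, fraction = 0), "fraction")
  expect_error(sample_frequencies(fixture_reads, 2, fraction = 1.5), "fraction")
})

test_that("sampling at fraction 1 equals the naive occurrence oracle; seeds reproduce", {
  for (m in c(2, 5)) {
    f <- sample_frequencies(fixture_reads, m, fraction = 1, seed = 3)
    o <- oracle_mmer_counts(fixture_reads$sequence, m)
    expect_equal(f$mmer, o$mmer)
    expect_equal(f$count, o$count)
  }
  a <- sample_frequencies(fixture_reads, 4, fraction = 0.3, seed = 9)
  b <- sample_frequencies(fixture_reads, 4, fraction = 0.3, seed = 9)
  expect_equal(a, b)
})

test_that("frequency ordering ranks rare before common with lexicographic ties", {
  tab <- tibble::tibble(code = encode_mer(c("AC", "GG", "TT")),
                        count = c(10L, 2L, 10L))
  o <- ordering_freq(tab, m = 2)
  r <- mmer_rank(o, c("GG", "AC", "TT"))
  expect_true(r[1] < r[2] && r[2] < r[3])
  # unseen m-mers (count 0) rank before all seen ones
  expect_lt(mmer_rank(o, "TA"), mmer_rank(o, "GG"))
  # equal counts degenerate to lexicographic
  flat <- tibble::tibble(code = 0:15, count = rep(4L, 16))
  of <- ordering_freq(flat, m = 2)
  expect_equal(order(mmer_rank(of, 0:15)), order(0:15))
})

test_that("frequency rank is monotone in sampled count on skewed data", {
  skew <- generate_reads(synth_spec(n_reads = 60, read_length = 80, seed = 21,
                                    motif_rate = 0.4, n_rate = 0))
  f <- sample_frequencies(skew, 4, fraction = 1, seed = 2)
  o <- ordering_freq(f)
  tidied <- f[order(mmer_rank(o, f$code)), ]
  expect_true(!is.unsorted(tidied$count))
  # A-rich m-mers dominate the sample and so get low priority (high rank)
  expect_gt(mmer_rank(o, "AAAA"), stats::median(mmer_rank(o, f$code)))
})

test_that("universal restriction never ranks a non-member above a member", {
  uhs <- generate_uhs(3, 6, seed = 4)
  base <- ordering_lex(3)
  o <- ordering_universal(base, uhs)
  r <- mmer_rank(o, 0:63)
  members <- 0:63 %in% uhs$members
  expect_lt(max(r[members]), min(r[!members]))
  # full set leaves the base ordering unchanged
  full <- kmerbin:::new_universal_set(0:63, 3, 6, "full")
  expect_equal(mmer_rank(ordering_universal(base, full), 0:63),
               mmer_rank(base, 0:63))
  expect_error(ordering_universal(ordering_lex(4), uhs), "does not match")
})

test_that("every ordering is an injective total order over all 4^m m-mers", {
  for (m in c(3, 6)) {
    k <- 2 * m
    codes <- 0:(4^m - 1)
    for (token in all_ordering_tokens) {
      o <- make_ordering(token, m, k, fixture_reads)
      r <- mmer_rank(o, codes)
      expect_equal(anyDuplicated(r), 0L, info = paste(token, "m =", m))
      expect_true(all(r >= 0 & r < o$span), info = token)
    }
  }
})

test_that("build_ordering validates its requirements", {
  expect_error(build_ordering("freq", 4), "needs reads")
  expect_error(build_ordering("ulex", 4), "hitting set")
  o <- build_ordering("signature", 5)
  expect_s3_class(o, "min_ordering")
})
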
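# Minimizer computation, canonical positions, super-k-mer parsing and the
# rolling (streaming) maintenance.

lex7 <- minimizer_scheme(7, 3, order = "lexicographic")

test_that("minimizers and canonical minimizers match hand-checked cases", {
  expect_equal(mini("TCAAGTT", lex7), list(mmer = "AAG", pos = 3))
  expect_equal(mini("AACTTGA", lex7), list(mmer = "AAC", pos = 1))
  expect_equal(mini("TTGGCCT", lex7), list(mmer = "CCT", pos = 5))

  # canonical: AAC (the minimizer of the reverse complement) begins in the
  # forward k-mer as its complement GTT at position 5
  expect_equal(cmini("TCAAGTT", lex7), list(mmer = "AAC", pos = 5))
  expect_equal(cmini("TTGGCCT", lex7)$mmer, "AGG")
  # the canonical value is strand-invariant
  set.seed(201)
  sch <- minimizer_scheme(11, 5, order = "random", seed = 3)
  for (x in r_random_kmers(200, 11)) {
    expect_identical(cmini(x, sch)$mmer, cmini(reverse_complement(x), sch)$mmer)
  }
})

test_that("lexicographic minimizer agrees with a full-scan oracle, leftmost on ties", {
  set.seed(202)
  sch <- minimizer_scheme(9, 3, order = "lexicographic")
  for (x in r_random_kmers(400, 9)) {
    expect_equal(mini(x, sch), r_mini_lex(x, 3))
  }
  # forced tie: repeated minimal m-mer, leftmost occurrence wins
  expect_equal(mini("ACGACGA", lex7), list(mmer = "ACG", pos = 1))
  expect_equal(mini("TTACGTACG", sch), list(mmer = "ACG", pos = 3))
})

test_that("rc_position flips occurrence positions between strands", {
  expect_equal(rc_position(7, 3, 1), 5)
  for (k in c(7, 15, 31)) {
    for (m in c(3, 5)) {
      p <- 1:(k - m + 1)
      expect_equal(rc_position(k, m, rc_position(k, m, p)), p) # involution
      expect_equal(rc_position(k, m, 1), k - m + 1)
    }
  }
  # string-search oracle on k-mers whose minimizer occurs uniquely
  set.seed(203)
  checked <- 0
  while (checked < 50) {
    x <- r_random_kmers(1, 15)
    h <- mini(x, minimizer_scheme(15, 5, order = "lexicographic"))
    if (length(gregexpr(h$mmer, x, fixed = TRUE)[[1]]) != 1) next
    rcpos <- regexpr(reverse_complement(h$mmer), reverse_complement(x), fixed = TRUE)
    if (rcpos < 0) next
    expect_equal(as.integer(rcpos), rc_position(15, 5, h$pos))
    checked <- checked + 1
  }
})

test_that("super-k-mers tile each string and respect the span bounds", {
  set.seed(204)
  for (mode in c("regular", "canonical")) {
    for (rep in 1:5) {
      s <- paste(sample(DNA, 500, TRUE), collapse = "")
      sch <- minimizer_scheme(31, 13, order = "random", seed = rep)
      df <- parse_super_kmers(s, sch, mode = mode)
      expect_equal(sum(df$n_kmers), nchar(s) - 31 + 1)    # exact tiling
      expect_true(all(df$n_kmers <= 31 - 13 + 1))          # <= k-m+1 k-mers
      expect_true(all(df$end - df$start + 1 <= 2 * 31 - 13)) # <= 2k-m chars
      expect_true(all(df$min_pos >= df$start))
      expect_true(all(df$min_pos + 13 - 1 <= df$end))
      # windows are contiguous across runs
      expect_equal(df$start[1], 1)
      expect_equal(df$start[-1], head(df$start, -1) + head(df$n_kmers, -1))
    }
  }
  # a string that is a single k-mer is a single super-k-mer
  one <- parse_super_kmers("ACGTACG", lex7)
  expect_equal(nrow(one), 1)
  expect_equal(one$n_kmers, 1)
})

test_that("sampled-position density matches the random-minimizer expectation", {
  # expected distinct sampled positions: 2/(k-m+2) * (N-m+1), within 10%
  N <- 1e5; k <- 31; m <- 13
  expected <- 2 / (k - m + 2) * (N - m + 1)
  set.seed(205)
  for (seed in 1:3) {
    s <- paste(sample(DNA, N, TRUE), collapse = "")
    df <- parse_super_kmers(s, minimizer_scheme(k, m, order = "random", seed = seed))
    observed <- length(unique(df$min_pos))
    expect_lt(abs(observed - expected) / expected, 0.10)
  }
})

test_that("rolling minimizers equal from-scratch computation on every window", {
  set.seed(206)
  for (ord in c("random", "lexicographic")) {
    sch <- minimizer_scheme(15, 5, order = ord, seed = 11)
    for (rep in 1:20) {
      s <- paste(sample(DNA, 80, TRUE), collapse = "")
      df <- streaming_minimizers(s, sch)
      wins <- substring(s, 1:(nchar(s) - 14), 15:nchar(s))
      for (w in seq_along(wins)) {
        expect_equal(list(mmer = df$fwd_mmer[w], pos = df$fwd_pos[w]),
                     mini(wins[w], sch))
        expect_equal(list(mmer = df$rc_mmer[w], pos = df$rc_pos[w]),
                     mini(reverse_complement(wins[w]), sch))
      }
    }
  }
  # constant sequence: every window samples A^m at position 1
  dfa <- streaming_minimizers(strrep("A", 30), minimizer_scheme(15, 5))
  expect_true(all(dfa$fwd_mmer == "AAAAA" & dfa$fwd_pos == 1))
})
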
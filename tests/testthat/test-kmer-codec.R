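# 2-bit codec, reverse complement and the packed SPSS.

test_that("encode/decode round-trips and matches the positional-sum oracle", {
  expect_equal(encode_kmer("AAAAAAA"), "0")
  expect_equal(decode_kmer(encode_kmer("ACGT"), 4), "ACGT")

  set.seed(101)
  for (k in c(5, 15, 31, 63)) {
    kms <- r_random_kmers(2500, k)
    expect_identical(decode_kmer(encode_kmer(kms), k), kms)
  }

  # brute-force per-character accumulator (exact decimal arithmetic)
  kms <- r_random_kmers(25, 31)
  expect_identical(encode_kmer(kms), vapply(kms, r_code_decimal, "", USE.NAMES = FALSE))
  kms63 <- r_random_kmers(10, 63)
  expect_identical(encode_kmer(kms63),
                   vapply(kms63, r_code_decimal, "", USE.NAMES = FALSE))

  expect_error(encode_kmer("ACGNT"), "position 4")
  expect_error(decode_kmer("16", 2), ">= 4\\^k")
})

test_that("reverse_complement is an involution agreeing with the character oracle", {
  expect_equal(reverse_complement("AACTTGA"), "TCAAGTT")
  expect_equal(reverse_complement("AAC"), "GTT")

  set.seed(102)
  kms <- r_random_kmers(5000, 21)
  rc <- reverse_complement(kms)
  expect_identical(rc, r_rc(kms))
  expect_identical(reverse_complement(rc), kms)
})

test_that("pack_spss concatenates with correct offsets and k-mer counts", {
  sp <- pack_spss(fig_spss(), k = 7)
  expect_equal(sp$N, 33)
  expect_equal(sp$P, c(1, 22, 34))
  expect_equal(sp$n_kmers, 21)

  one <- pack_spss("ACGTACG", k = 7)
  expect_equal(one$N, 7)
  expect_equal(one$P, c(1, 8))
  expect_equal(one$n_kmers, 1)

  expect_error(pack_spss(c("ACGTACG", "ACG"), k = 7), "length 3 < k")
  # duplicated k-mer (as reverse complement) names both occurrences
  expect_error(pack_spss(c("AACTTGAC", "GTCAAGTT"), k = 7),
               "string 1 position 2 and string 2 position 1")
  expect_error(pack_spss("ACGTNCG", k = 7), "non-ACGT")
})

test_that("extract agrees with plain-string slicing", {
  s <- fig_spss()
  sp <- pack_spss(s, k = 7)
  cat_s <- paste(s, collapse = "")
  expect_equal(spss_extract(sp, 1, sp$N), cat_s)
  expect_equal(spss_extract(sp, 1, 7), "TCAAGTT")

  set.seed(103)
  for (i in 1:300) {
    q <- sample(sp$N, 1)
    w <- sample(sp$N - q + 1, 1)
    expect_equal(spss_extract(sp, q, w), substr(cat_s, q, q + w - 1))
  }
  expect_error(spss_extract(sp, 30, 7), "out of range")
  expect_error(spss_extract(sp, 0, 3), "out of range")
})
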
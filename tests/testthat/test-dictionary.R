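# Index assembly, LOOKUP, ACCESS, displacements and space accounting.

test_that("the worked lookup example resolves through the reverse complement", {
  d <- build_index(fig_spss(), k = 7, m = 3, mode = "regular",
                   order = "lexicographic", seed = 1)
  res <- lookup(d, "AACTTGA")
  expect_equal(res$handle, 1)      # TCAAGTT is the first k-mer of string 1
  expect_equal(res$position, 1)
  expect_equal(res$orientation, -1)
  expect_true(res$found)
})

test_that("regular and canonical displacements match the worked examples", {
  sch <- minimizer_scheme(7, 3, order = "lexicographic")
  expect_equal(displace_regular(27, mini("AACTTGA", sch)$pos), 27)
  expect_equal(displace_regular(3, mini("TCAAGTT", sch)$pos), 1)
  expect_equal(displace_regular(10, 1), 10)

  dc <- displace_canonical("TTGGCCT", 10, sch)
  expect_setequal(dc$q, c(10, 6))
  expect_equal(dc$q[dc$orientation == 1], 6) # the forward candidate matches S

  # a k-mer whose two strands share the same (palindromic) minimizer CCGG
  # emits all four candidates
  dpal <- displace_canonical("GCCGGCG", 20, minimizer_scheme(7, 4,
                                                            order = "lexicographic"))
  expect_equal(nrow(dpal), 4)
  # candidates that would start before position 1 are dropped
  expect_lte(nrow(displace_canonical("TTGGCCT", 1, sch)), 2)
})

test_that("displacement candidates contain the true position, both strands", {
  sp <- gen_spss(3000, 3, 15, seed = 31)
  sch <- minimizer_scheme(15, 7, order = "random", seed = 31)
  d <- build_index(sp$strings, 15, 7, mode = "canonical", seed = 31)
  cat_s <- paste(sp$strings, collapse = "")
  idx <- seq(1, nrow(sp$truth), by = 17)
  offs <- c(0, cumsum(nchar(sp$strings)))
  for (i in idx) {
    x <- sp$truth$kmer[i]
    q_true <- offs[sp$truth$string_id[i]] + sp$truth$position[i]
    j <- q_true + cmini(x, sch)$pos - 1 # stored occurrence for this k-mer
    for (qq in list(displace_canonical(x, j, sch),
                    displace_canonical(reverse_complement(x), j, sch))) {
      expect_true(q_true %in% qq$q)
    }
  }
})

test_that("handles are a minimal order-preserving bijection (both modes)", {
  cases <- list(list(G = 350, S = 3, k = 7, m = 3),
                list(G = 20000, S = 8, k = 31, m = 13))
  for (cs in cases) {
    sp <- gen_spss(cs$G, cs$S, cs$k, seed = 51, rc_fraction = 0.3)
    for (mode in c("canonical", "regular")) {
      for (seed in c(1, 2)) {
        d <- build_index(sp$strings, cs$k, cs$m, mode = mode, seed = seed)
        res <- lookup(d, sp$truth$kmer)
        n <- nrow(sp$truth)
        expect_identical(sort(res$handle), as.numeric(1:n))
        # consecutive k-mers of a string get consecutive handles
        same <- sp$truth$string_id[-1] == head(sp$truth$string_id, -1)
        expect_true(all((res$handle[-1] - head(res$handle, -1))[same] == 1))
        # strand coherence
        res2 <- lookup(d, reverse_complement(sp$truth$kmer))
        expect_identical(res2$handle, res$handle)
        expect_true(all(res2$orientation == -res$orientation))
        # no window crosses a string boundary
        P <- c(1, cumsum(nchar(sp$strings)) + 1)
        i <- findInterval(res$position, P)
        expect_true(all(res$position + cs$k - 1 <= P[i + 1] - 1))
      }
    }
  }
})

test_that("access inverts lookup and handles out of range give epsilon", {
  sp <- gen_spss(5000, 5, 21, seed = 52)
  d <- build_index(sp$strings, 21, 9, seed = 52)
  n <- index_stats(d)$n
  expect_equal(access_kmer(d, 1), substr(sp$strings[1], 1, 21))
  expect_equal(access_kmer(d, n + 1), "")
  expect_equal(access_kmer(d, c(0, -3)), c("", ""))
  idx <- seq(1, nrow(sp$truth), by = 7)
  res <- lookup(d, sp$truth$kmer[idx])
  back <- access_kmer(d, res$handle)
  expect_true(all(back == sp$truth$kmer[idx] |
                  back == reverse_complement(sp$truth$kmer[idx])))
})

test_that("absent k-mers are never reported present", {
  sp <- gen_spss(20000, 10, 31, seed = 53)
  d <- build_index(sp$strings, 31, 13, seed = 53)
  set.seed(530)
  cand <- r_random_kmers(20000, 31)
  absent <- !kmer_membership(sp$strings, 31, cand)
  res <- lookup(d, cand[absent])
  expect_true(all(is.na(res$handle)))
  # lookup of a k-mer with non-ACGT characters is a miss, not an error
  expect_true(is.na(lookup(d, paste0(strrep("A", 30), "N"))$handle))
  # a wrong-length query is a parameter error, distinct from a miss
  expect_error(lookup(d, "ACGT"), "length")
})

test_that("space accounting reports the exactly-determined terms", {
  sp <- gen_spss(20000, 5, 31, seed = 54)
  for (m in c(7, 15)) { # m = 7 forces light/heavy sets, m = 15 mostly singletons
    d <- build_index(sp$strings, 31, m, seed = 54)
    i <- index_stats(d)
    sr <- space_report(d)
    bits <- setNames(sr$bits, sr$component)
    pw <- ceiling(log2(i$N))
    expect_equal(bits[["S"]], 2 * i$N)
    if (!i$tag_widened) expect_equal(bits[["T"]], i$M * (pw + 1))
    expect_equal(bits[["L"]] + bits[["H"]], (i$Z - i$n_singleton) * pw)
    if (i$alpha == 0) expect_equal(bits[["skew"]], 0)
    expect_equal(attr(sr, "bits_per_kmer"), sum(sr$bits) / i$n)
  }
})

test_that("locate sets cover every super-k-mer and build rejects bad input", {
  sp <- gen_spss(20000, 5, 31, seed = 55)
  for (mode in c("regular", "canonical")) {
    d <- build_index(sp$strings, 31, 11, mode = mode, seed = 55)
    i <- index_stats(d)
    runs <- sum(vapply(sp$strings, function(s) {
      nrow(parse_super_kmers(s, minimizer_scheme(31, 11, seed = 55), mode))
    }, 0))
    expect_equal(i$n_super_kmers, runs)
    expect_equal(i$Z, runs) # distinct (minimizer, position) pairs here
  }
  expect_error(build_index(sp$strings, 31, 31, seed = 1), "m must")
  expect_error(build_index(c("AACTTGAC", "GTCAAGTT"), 7, 3), "duplicate k-mer")
  expect_error(build_index("ACG", 7, 3), "shorter than k")
})

test_that("serialization round-trips and builds are byte-deterministic", {
  sp <- gen_spss(8000, 4, 31, seed = 56)
  d1 <- build_index(sp$strings, 31, 13, seed = 56)
  d2 <- build_index(sp$strings, 31, 13, seed = 56)
  f1 <- tempfile(); f2 <- tempfile()
  info <- save_index(d1, f1)
  save_index(d2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_equal(file.size(f1), info$bytes)
  expect_equal(sum(info$component_bytes), info$bytes)
  d3 <- load_index(f1)
  q <- sp$truth$kmer[seq(1, nrow(sp$truth), 3)]
  expect_identical(lookup(d1, q), lookup(d3, q))
  expect_identical(index_stats(d1), index_stats(d3))
  # corrupt magic bytes are rejected
  writeBin(as.raw(1:64), f2)
  expect_error(load_index(f2), "magic")
  unlink(c(f1, f2))
})
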
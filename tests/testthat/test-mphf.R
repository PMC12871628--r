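# Minimal perfect hashing: bijection, determinism, foreign keys.

test_that("mphf is a bijection onto 1..M across sizes and seeds", {
  expect_equal(mphf_eval(mphf_build(42), 42), 1)
  set.seed(401)
  for (M in c(1, 10, 1000, 100000)) {
    keys <- r_random_keys(M)
    for (seed in c(1, 7, 99)) {
      f <- mphf_build(keys, seed = seed)
      expect_identical(sort(mphf_eval(f, keys)), as.numeric(seq_len(M)))
    }
  }
})

test_that("foreign keys stay in range and evaluation is deterministic", {
  set.seed(402)
  keys <- r_random_keys(5000)
  f1 <- mphf_build(keys, seed = 5)
  f2 <- mphf_build(keys, seed = 5)
  foreign <- r_random_keys(10000)
  v1 <- mphf_eval(f1, foreign)
  expect_true(all(v1 >= 1 & v1 <= 5000))
  expect_identical(v1, mphf_eval(f2, foreign))        # same seed, same function
  expect_identical(f1$blob, f2$blob)                  # serialized tables identical

  expect_error(mphf_build(c(3, 3, 5)), "distinct")
  expect_error(mphf_build(numeric(0)))
})

test_that("space stays above the information-theoretic floor", {
  set.seed(403)
  f <- mphf_build(r_random_keys(50000), seed = 2)
  expect_gte(f$bits_per_key, log2(exp(1)))
  expect_lt(f$bits_per_key, 8) # bucket placement stays within a few bits/key
})
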
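# Elias-Fano sequences: lossless access, successor, size bound.

test_that("ef round-trips arrays exactly", {
  e <- ef_build(c(1, 22, 34), U = 34)
  expect_equal(ef_access(e, 1:3), c(1, 22, 34))

  e0 <- ef_build(0, U = 0)
  expect_equal(ef_access(e0, 1), 0)

  set.seed(301)
  for (rep in 1:10) {
    n <- sample(1:10000, 1)
    U <- n * sample(1:50, 1)
    a <- sort(sample(0:U, n, replace = TRUE))
    e <- ef_build(a, U)
    expect_identical(ef_access(e, seq_len(n)), as.numeric(a))
    probes <- sample(n, min(n, 200))
    expect_identical(ef_access(e, probes), as.numeric(a[probes]))
  }
  expect_error(ef_build(c(3, 1), 5), "sorted")
  expect_error(ef_build(c(1, 9), 5), "universe")
  expect_error(ef_access(ef_build(c(1, 2), 2), 3), "out of range")
})

test_that("successor matches a linear-scan oracle exhaustively", {
  set.seed(302)
  for (rep in 1:5) {
    n <- sample(50:400, 1)
    U <- sample(500:3000, 1)
    a <- sort(sample(0:U, n, replace = TRUE))
    e <- ef_build(a, U)
    xs <- 0:max(a)
    got <- ef_successor(e, xs)
    idx <- r_successor_idx(a, xs)
    expect_identical(got$index, as.numeric(idx))
    expect_identical(got$value, as.numeric(a[idx]))
  }
  # large array, sampled probes
  a <- sort(sample(0:1e6, 1e4))
  e <- ef_build(a, 1e6)
  xs <- sort(sample(0:max(a), 3000))
  got <- ef_successor(e, xs)
  idx <- r_successor_idx(a, xs)
  expect_identical(got$index, as.numeric(idx))

  expect_error(ef_successor(e, max(a) + 1), "exceeds the last element")
})

test_that("duplicates take the leftmost index and the size bound holds", {
  a <- c(2, 5, 5, 5, 9)
  e <- ef_build(a, 9)
  expect_equal(ef_successor(e, 5)$index, 2)
  # successor(access(i)) lands at an index <= i with equal value
  for (i in seq_along(a)) {
    s <- ef_successor(e, a[i])
    expect_lte(s$index, i)
    expect_equal(s$value, a[i])
  }

  set.seed(303)
  for (rep in 1:10) {
    n <- sample(2:5000, 1)
    U <- n * sample(1:1000, 1)
    a <- sort(sample(0:U, n, replace = TRUE))
    sz <- ef_size_bits(ef_build(a, U))
    bound <- n * log2(U / n) + 3 * n
    expect_lte(sz$total_bits, bound + sz$select_overhead_bits)
  }
})
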
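# Streaming lookup: state carry-over, extensions, budget, negative skips.

stream_fixture <- function(seed = 61) {
  sp <- gen_spss(20000, 10, 31, seed = seed)
  list(sp = sp,
       dicts = list(canonical = build_index(sp$strings, 31, 13,
                                            mode = "canonical", seed = seed),
                    regular = build_index(sp$strings, 31, 13,
                                          mode = "regular", seed = seed)))
}

per_window_oracle <- function(d, reads, k = 31) {
  wins <- unlist(lapply(reads, function(r) {
    substring(r, 1:(nchar(r) - k + 1), k:nchar(r))
  }))
  lookup(d, wins)
}

test_that("an exact read seeds once and extends through every other window", {
  fx <- stream_fixture()
  r <- substr(fx$sp$strings[1], 11, 140) # 130 bp, 100 windows
  for (d in fx$dicts) {
    out <- stream_lookup(d, r, budget = 1e6)
    st <- stream_stats(out)
    expect_equal(st$seeds, 1)
    expect_equal(st$extensions, 130 - 31)
    expect_equal(st$extension_rate, (130 - 31) / (130 - 31 + 1))
    expect_equal(out$handle, out$handle[1] + 0:(130 - 31)) # consecutive handles
    expect_true(all(out$orientation == 1))
  }
})

test_that("a reverse-complement read extends with decreasing handles", {
  fx <- stream_fixture()
  r <- reverse_complement(substr(fx$sp$strings[2], 1, 100))
  for (d in fx$dicts) {
    out <- stream_lookup(d, r)
    expect_true(all(out$orientation == -1))
    expect_equal(out$handle, out$handle[1] - 0:(100 - 31))
    orc <- per_window_oracle(d, r)
    expect_identical(out$handle, orc$handle)
  }
})

test_that("streaming output equals per-window lookup on mixed reads", {
  fx <- stream_fixture()
  rs <- gen_reads(fx$sp$strings, 800, 120, sub_rate = 0.01,
                  foreign_fraction = 0.15, rc_fraction = 0.5, seed = 62)
  for (mode in names(fx$dicts)) {
    d <- fx$dicts[[mode]]
    orc <- per_window_oracle(d, rs$reads)
    for (budget in c(32, 0)) {
      out <- stream_lookup(d, rs$reads, budget = budget)
      expect_identical(out$handle, orc$handle)
      expect_identical(out$position, orc$position)
      expect_identical(out$orientation, orc$orientation)
      expect_identical(out$found, orc$found)
      st <- stream_stats(out)
      expect_equal(st$extensions + st$seeds + st$skipped + st$invalid,
                   st$windows)
      if (budget == 0) expect_equal(st$extensions, 0)
    }
  }
})

test_that("error-crossing windows force re-seeding but not wrong answers", {
  fx <- stream_fixture()
  d <- fx$dicts$canonical
  # plant substitutions at known positions of an exact read
  r <- substr(fx$sp$strings[3], 1, 150)
  rr <- strsplit(r, "")[[1]]
  for (p in c(40, 90)) rr[p] <- setdiff(DNA, rr[p])[1]
  r <- paste(rr, collapse = "")
  out <- stream_lookup(d, r)
  orc <- per_window_oracle(d, r)
  expect_identical(out$handle, orc$handle)
  # every window crossing an error is a miss (substituted k-mers are foreign)
  miss <- which(is.na(orc$handle))
  covers <- sort(unique(c(outer(c(40, 90), 0:30, "-"))))
  covers <- covers[covers >= 1 & covers <= 120]
  expect_true(all(covers %in% miss))
  expect_gte(stream_stats(out)$seeds, 2)
})

test_that("foreign reads yield no positives and non-ACGT windows are invalid", {
  fx <- stream_fixture()
  d <- fx$dicts$canonical
  rs <- gen_reads(fx$sp$strings, 100, 100, foreign_fraction = 1, seed = 63)
  out <- stream_lookup(d, rs$reads)
  expect_equal(stream_stats(out)$positive, 0)
  expect_true(all(is.na(out$handle)))

  r <- substr(fx$sp$strings[4], 1, 100)
  substr(r, 50, 50) <- "N"
  out <- stream_lookup(d, r)
  inv <- which(!out$valid)
  expect_equal(inv, 20:50) # windows covering position 50
  expect_true(all(is.na(out$handle[inv])))
  # windows before/after the bad base still resolve
  expect_true(all(!is.na(out$handle[-inv])))

  expect_error(stream_lookup(d, "ACGT"), "shorter than k")
})

test_that("a high-hit workload has mostly positive windows", {
  fx <- stream_fixture()
  rs <- gen_reads(fx$sp$strings, 2000, 150, sub_rate = 0.01,
                  foreign_fraction = 0, seed = 64)
  out <- stream_lookup(fx$dicts$canonical, rs$reads)
  expect_gt(mean(!is.na(out$handle)), 0.75)
})
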
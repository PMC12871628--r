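# Three-type locate-set layout: tags, light groups, heavy skew index.

make_layout_fixture <- function(l = 6, seed = 1) {
  # sizes 1, 2, 3, 2^l (largest light) and 2^l + 1 (smallest heavy)
  sizes <- c(1, 2, 3, 2^l, 2^l + 1)
  mmers <- c("AAACC", "AAAGG", "AAATT", "AACCC", "AAGGG")
  pos <- 1
  occ <- list()
  for (i in seq_along(sizes)) {
    occ[[mmers[i]]] <- seq(pos, by = 7, length.out = sizes[i])
    pos <- max(occ[[mmers[i]]]) + 7
  }
  z <- 2^l + 1
  hk <- list(list(kmers = gen_spss(z + 14, 1, 15, seed = seed)$truth$kmer,
                  loc_index = seq_len(z)))
  names(hk) <- mmers[5]
  N <- max(unlist(occ)) + 20
  list(occ = occ, heavy = hk, N = N,
       layout = build_layout(occ, hk, l = l, N = N, seed = seed))
}

test_that("every locate set is retrievable bit-exactly through its tag", {
  fx <- make_layout_fixture()
  lay <- fx$layout
  expect_equal(lay$M, 5)
  expect_equal(lay$n_singleton, 1)
  for (nm in names(fx$occ)[1:4]) {
    lo <- layout_locate(lay, nm)
    expect_identical(sort(lo$candidates), as.numeric(fx$occ[[nm]]))
  }
  # heavy set: one candidate per k-mer, the entry its loc_index points at
  hk <- fx$heavy[[1]]
  for (t in seq_along(hk$kmers)) {
    lo <- layout_locate(lay, names(fx$heavy), hk$kmers[t])
    expect_equal(lo$type, "heavy")
    expect_equal(lo$candidates, fx$occ[[names(fx$heavy)]][hk$loc_index[t]])
  }
})

test_that("probe counts honour the singleton/light/heavy contract", {
  fx <- make_layout_fixture()
  lay <- fx$layout
  lo <- layout_locate(lay, "AAACC")
  expect_equal(lo$type, "singleton")
  expect_equal(lo$probes$L + lo$probes$H, 0)  # answered from the tag alone
  for (nm in c("AAAGG", "AAATT", "AACCC")) {
    lo <- layout_locate(lay, nm)
    expect_equal(lo$type, "light")
    expect_equal(lo$probes$L, length(fx$occ[[nm]]))
    expect_lte(lo$probes$L, 2^6)
    expect_equal(lo$probes$H, 0)
  }
  lo <- layout_locate(lay, names(fx$heavy), fx$heavy[[1]]$kmers[10])
  expect_equal(lo$probes$H, 1)  # one entry of H ...
  expect_equal(lo$probes$V, 1)  # ... plus one of V_i
  expect_equal(lo$probes$L, 0)
})

test_that("space accounting is exact and the tag decodes the right type", {
  fx <- make_layout_fixture()
  lay <- fx$layout
  Z <- sum(lengths(fx$occ))
  expect_equal(lay$bits$T, lay$M * lay$tag_width)
  expect_equal(lay$L_entries + lay$H_entries, Z - lay$n_singleton)
  expect_equal(lay$bits$L + lay$bits$H, (Z - lay$n_singleton) * lay$pos_width)
  types <- vapply(names(fx$occ), function(nm) layout_locate(lay, nm)$type, "")
  expect_identical(unname(types),
                   c("singleton", "light", "light", "light", "heavy"))
})

test_that("skew partitioning follows the size-class rule", {
  l <- 6; r <- 13
  expect_equal(skew_partition_of(2^l + 1, l, r), l)       # first boundary
  expect_equal(skew_partition_of(2^(l + 1), l, r), l)
  expect_equal(skew_partition_of(2^(l + 1) + 1, l, r), l + 1)
  expect_equal(skew_partition_of(2^(r + 1) + 5, l, r), r) # clamp
  # against a loop over i
  for (z in c(65, 100, 129, 1000, 5000, 20000)) {
    i <- l
    while (i < r && z > 2^(i + 1)) i <- i + 1
    expect_equal(skew_partition_of(z, l, r), i)
  }
  expect_error(skew_partition_of(64, l, r), "exceed")
  expect_error(build_layout(list(AAA = 1), l = 2, r = 12, N = 10), "3 bits")
})

test_that("tiny inputs widen the tag word instead of failing", {
  # N = 40 gives 6 position bits, too few for l = 6 light fields
  occ <- list(AAACC = c(1), AAAGG = c(5, 12), AAATT = c(3, 20, 31))
  lay <- build_layout(occ, l = 6, N = 40, seed = 2)
  expect_true(lay$widened)
  expect_gt(lay$tag_width, lay$pos_width + 1)
  for (nm in names(occ)) {
    expect_identical(sort(layout_locate(lay, nm)$candidates),
                     as.numeric(occ[[nm]]))
  }
})
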
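# Synthetic data generation, FASTA/FASTQ round trips, CLI.

test_that("gen_spss is deterministic and honours the SPSS contract", {
  a <- gen_spss(4000, 5, 21, seed = 9)
  b <- gen_spss(4000, 5, 21, seed = 9)
  expect_identical(a$strings, b$strings)
  expect_false(identical(a$strings, gen_spss(4000, 5, 21, seed = 10)$strings))

  expect_equal(sum(nchar(a$strings)), 4000)
  expect_equal(nrow(a$truth), sum(nchar(a$strings) - 21 + 1))
  # no duplicate k-mers up to reverse complement
  canon <- pmin(a$truth$kmer, reverse_complement(a$truth$kmer))
  expect_false(any(duplicated(canon)))
  # truth table is correct by direct substring check
  idx <- sample(nrow(a$truth), 50)
  expect_identical(a$truth$kmer[idx],
                   substr(a$strings[a$truth$string_id[idx]],
                          a$truth$position[idx], a$truth$position[idx] + 20))

  expect_error(gen_spss(50, 5, 21), "too small")
  # a 33-base, 2-string set at k = 7 carries exactly 21 k-mers
  expect_equal(nrow(gen_spss(33, 2, 7, seed = 3)$truth), 21)
})

test_that("gen_reads labels follow the generating process", {
  sp <- gen_spss(10000, 5, 31, seed = 21)
  rs <- gen_reads(sp$strings, 400, 100, sub_rate = 0, foreign_fraction = 0,
                  seed = 22)
  # error-free reads: every window present in the k-mer set
  present <- kmer_membership(sp$strings,  31,
                             unlist(lapply(rs$reads, function(r) {
                               substring(r, 1:70, 31:100)
                             })))
  expect_true(all(present))
  # reads trace back to their recorded origin
  idx <- which(!rs$origin$revcomp)[1:20]
  expect_identical(rs$reads[idx],
                   substr(sp$strings[rs$origin$string_id[idx]],
                          rs$origin$start[idx], rs$origin$start[idx] + 99))

  # all-foreign reads essentially never hit (collision odds <= n / 4^k)
  rf <- gen_reads(sp$strings, 200, 100, foreign_fraction = 1, seed = 23)
  hits <- kmer_membership(sp$strings, 31,
                          unlist(lapply(rf$reads, function(r) {
                            substring(r, 1:70, 31:100)
                          })))
  expect_equal(mean(hits), 0)
  expect_identical(rs$reads, gen_reads(sp$strings, 400, 100, sub_rate = 0,
                                       foreign_fraction = 0, seed = 22)$reads)
})

test_that("the membership oracle agrees with substring enumeration", {
  set.seed(24)
  strings <- r_random_kmers(3, 40)
  queries <- c(substring(strings[1], 3, 17),
               reverse_complement(substring(strings[2], 5, 19)),
               r_random_kmers(30, 15))
  expect_identical(kmer_membership(strings, 15, queries, canonical = TRUE),
                   r_membership(strings, 15, queries, canonical = TRUE))
  expect_identical(kmer_membership(strings, 15, queries, canonical = FALSE),
                   r_membership(strings, 15, queries, canonical = FALSE))
})

test_that("FASTA and FASTQ round-trip, including gzip", {
  sp <- gen_spss(2000, 4, 21, seed = 25)
  fa <- tempfile(fileext = ".fa")
  write_spss_fasta(sp$strings, fa)
  expect_identical(unname(read_spss_fasta(fa)), sp$strings)

  rs <- gen_reads(sp$strings, 30, 60, seed = 26)
  for (ext in c(".fastq", ".fastq.gz")) {
    fq <- tempfile(fileext = ext)
    write_reads_fastq(rs$reads, fq)
    expect_identical(read_reads_fastq(fq), rs$reads)
    unlink(fq)
  }
  unlink(fa)
})

test_that("the CLI drives build, stats, access and streaming queries", {
  sp <- gen_spss(5000, 5, 31, seed = 27)
  fa <- tempfile(fileext = ".fa"); ix <- tempfile(fileext = ".kdx")
  fq <- tempfile(fileext = ".fastq.gz")
  write_spss_fasta(sp$strings, fa)
  write_reads_fastq(gen_reads(sp$strings, 20, 80, seed = 28)$reads, fq)

  expect_equal(run_cli(c("build", "-i", fa, "-k", "31", "-m", "13", "-o", ix)), 0L)
  d <- load_index(ix)
  expect_equal(index_stats(d)$n, nrow(sp$truth))
  # stats breakdown: serialized component bytes sum to the file size
  info <- save_index(d, ix)
  expect_equal(sum(info$component_bytes), file.size(ix))

  expect_equal(run_cli(c("stats", "-x", ix)), 0L)
  expect_output(run_cli(c("access", "-x", ix, "--handle", "1")),
                substr(sp$strings[1], 1, 31))
  expect_equal(run_cli(c("query", "-x", ix, "-q", fq, "--streaming")), 0L)
  expect_equal(run_cli(c("query", "-x", ix, "--kmer", sp$truth$kmer[5])), 0L)
  # usage errors exit non-zero
  expect_equal(run_cli(c("query", "-x", ix, "--kmer", "ACGT")), 1L)
  expect_equal(run_cli(c("frobnicate")), 1L)
  expect_equal(run_cli(character(0)), 1L)
  unlink(c(fa, ix, fq))
})

test_that("save/load/query round trip re-verifies lookups", {
  sp <- gen_spss(6000, 4, 31, seed = 29)
  d <- build_index(sp$strings, 31, 15, seed = 29)
  ix <- tempfile(fileext = ".kdx")
  save_index(d, ix)
  d2 <- load_index(ix)
  q <- c(sp$truth$kmer[seq(1, nrow(sp$truth), 6)])
  expect_identical(lookup(d, q), lookup(d2, q))
  unlink(ix)
})
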
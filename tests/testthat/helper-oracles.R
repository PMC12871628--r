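# Pure-R reference oracles, independent of the compiled code paths.

DNA <- c("A", "C", "G", "T")

# vectorized random k-mers (caller sets the RNG seed)
r_random_kmers <- function(n, k) {
  m <- matrix(sample(DNA, n * k, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# character-level reverse complement
r_rc <- function(s) {
  vapply(s, function(x) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
  }, "", USE.NAMES = FALSE)
}

# all m-mers of x, leftmost first
r_mmers <- function(x, m) {
  k <- nchar(x)
  substring(x, 1:(k - m + 1), m:k)
}

# full-scan lexicographic minimizer: leftmost minimal m-mer
r_mini_lex <- function(x, m) {
  mm <- r_mmers(x, m)
  pos <- which(mm == min(mm))[1]
  list(mmer = mm[pos], pos = pos)
}

# big-integer decimal accumulator: value of sum(digit * 4^(pos-1)) as a
# decimal string, via Horner from the last position down
r_code_decimal <- function(x) {
  d <- match(strsplit(x, "")[[1]], DNA) - 1L
  mul4add <- function(dec, add) {
    v <- as.integer(rev(strsplit(dec, "")[[1]]))
    v <- v * 4L
    v[1] <- v[1] + add
    carry <- 0L
    out <- integer(0)
    i <- 1
    while (i <= length(v) || carry > 0L) {
      t <- (if (i <= length(v)) v[i] else 0L) + carry
      out <- c(out, t %% 10L)
      carry <- t %/% 10L
      i <- i + 1
    }
    paste(rev(out), collapse = "")
  }
  dec <- "0"
  for (p in rev(seq_along(d))) dec <- mul4add(dec, d[p])
  sub("^0+(?=.)", "", dec, perl = TRUE)
}

# leftmost successor by linear scan
r_successor <- function(a, x) {
  i <- which(a >= x)[1]
  list(index = i, value = a[i])
}

# vectorized leftmost-successor index for sorted integer arrays
r_successor_idx <- function(a, x) findInterval(x - 0.5, a) + 1L

# membership by plain substring enumeration (tiny inputs only)
r_membership <- function(strings, k, queries, canonical = TRUE) {
  kms <- unlist(lapply(strings, function(s) {
    substring(s, 1:(nchar(s) - k + 1), k:nchar(s))
  }))
  if (canonical) kms <- unique(c(kms, r_rc(kms)))
  queries %in% kms
}

# distinct random integer keys below 2^48
r_random_keys <- function(n) {
  keys <- floor(runif(n, 0, 2^48))
  while (anyDuplicated(keys)) {
    keys <- unique(keys)
    keys <- c(keys, floor(runif(n - length(keys), 0, 2^48)))
  }
  keys
}

# a small SPSS whose first string starts with TCAAGTT, two strings of
# lengths 21 and 12 (33 bases, 21 7-mers) with no repeated canonical 7-mer
fig_spss <- function() c("TCAAGTTACTGGACTTTGACC", "GCACGGTATCAG")
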
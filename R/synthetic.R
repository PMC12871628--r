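# Synthetic SPSS and read-set generation, plus a reference membership
# oracle used throughout the test suite.

#' Generate a synthetic SPSS
#'
#' Emulates the output of a compaction pipeline (unitigs/eulertigs): DNA
#' strings of length >= k whose k-mers are pairwise distinct up to reverse
#' complement.  Bases are drawn uniformly; each appended base is checked
#' against the canonical k-mers emitted so far and a string is restarted in
#' the rare event that no base can extend it, so the SPSS contract holds by
#' construction.  Deterministic given the seed.
#'
#' @param total_bases total number of bases over all strings.
#' @param n_strings number of strings (bases are split as evenly as
#'   possible).
#' @param k k-mer length.
#' @param seed integer seed.
#' @param rc_fraction fraction of strings stored reverse-complemented
#'   (exercises strand handling; the k-mer content is unchanged).
#' @param truth also return the truth table mapping every k-mer to its
#'   string and position (default TRUE).
#' @return list with `strings`, `k`, and (when `truth`) a data.frame
#'   `truth` with columns `kmer`, `string_id`, `position`.
#' @examples
#' sp <- gen_spss(400, n_strings = 2, k = 21, seed = 1)
#' nchar(sp$strings)
#' nrow(sp$truth)   # sum(lengths) - n_strings*(k-1)
#' @export
gen_spss <- function(total_bases, n_strings, k, seed = 1, rc_fraction = 0,
                     truth = TRUE) {
  strings <- cpp_gen_spss(as.numeric(total_bases), as.integer(n_strings),
                          as.integer(k), as.numeric(seed), rc_fraction)
  out <- list(strings = strings, k = as.integer(k))
  if (isTRUE(truth)) out$truth <- cpp_enumerate_kmers(strings, as.integer(k))
  out
}

#' Generate a synthetic read set from an SPSS
#'
#' Reads are windows sampled uniformly from the strings (weighted by the
#' number of windows each string offers), optionally reverse-complemented
#' and perturbed with substitution errors; a fraction of reads is fully
#' random ("foreign").  Deterministic given the seed.
#'
#' @param strings SPSS strings (or the list returned by [gen_spss()]).
#' @param n_reads number of reads.
#' @param read_length read length (>= k for streaming queries).
#' @param sub_rate per-base substitution probability.
#' @param foreign_fraction fraction of fully random reads.
#' @param rc_fraction fraction of sampled reads stored reverse-complemented.
#' @param seed integer seed.
#' @return list with `reads` and a data.frame `origin` (`string_id` and
#'   `start` are NA for foreign reads; `revcomp`, `foreign`,
#'   `n_substitutions`).
#' @export
gen_reads <- function(strings, n_reads, read_length, sub_rate = 0,
                      foreign_fraction = 0, rc_fraction = 0.5, seed = 1) {
  if (is.list(strings)) strings <- strings$strings
  stopifnot(is.character(strings))
  cpp_gen_reads(strings, as.numeric(n_reads), as.numeric(read_length),
                sub_rate, foreign_fraction, rc_fraction, as.numeric(seed))
}

#' Reference k-mer membership oracle
#'
#' A plain hash set over all k-mers of `strings`, queried directly --
#' independent of the dictionary data path, which makes it suitable as an
#' oracle when validating [lookup()] results.
#'
#' @param strings character vector of DNA strings.
#' @param k k-mer length.
#' @param queries character vector of query k-mers.
#' @param canonical when TRUE (default) a query matches if the k-mer or
#'   its reverse complement occurs.
#' @return logical vector, one entry per query.
#' @export
kmer_membership <- function(strings, k, queries, canonical = TRUE) {
  cpp_kmer_membership(toupper(strings), as.integer(k), toupper(queries),
                      isTRUE(canonical))
}

#' Enumerate the k-mers of a set of strings
#'
#' @param strings character vector of DNA strings.
#' @param k k-mer length.
#' @return data.frame with columns `kmer`, `string_id`, `position`.
#' @export
enumerate_kmers <- function(strings, k) {
  cpp_enumerate_kmers(toupper(strings), as.integer(k))
}
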
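# Index assembly, LOOKUP, ACCESS and space accounting.

#' Build a k-mer dictionary over an SPSS
#'
#' Parses the packed concatenation `S` into super-k-mers, collects for
#' every minimizer its locate set (the sorted distinct absolute positions
#' of its sampled occurrences, one per super-k-mer), builds a minimal
#' perfect hash function over the minimizer set, lays the locate sets out
#' in the three-type tag structure with a skew index for heavy minimizers
#' (see [build_layout()]), and codes the string offsets `P` with
#' Elias-Fano.
#'
#' In the `"regular"` modality minimizers of the forward k-mer are used and
#' a failed lookup is retried with the reverse complement; in the
#' `"canonical"` modality (the default) a k-mer and its reverse complement
#' share the same canonical minimizer, so a single pass answers both
#' strands at the price of slightly denser sampling.
#'
#' @param strings character vector: the SPSS (every string of length >= k,
#'   no k-mer repeated across strings, up to reverse complement).
#' @param k k-mer length (2--63).
#' @param m minimizer length (`m < k`, `m <= 31`).
#' @param mode `"canonical"` or `"regular"`.
#' @param order minimizer order, `"random"` (default) or
#'   `"lexicographic"`.
#' @param seed seed for the random order and the hash functions; recorded
#'   in the index header.
#' @param l light/heavy threshold exponent (default 6).
#' @param r top skew partition (default `l + 7`, at most 8 partitions).
#' @return an object of class `"kmer_dict"`.
#' @examples
#' sp <- gen_spss(2000, n_strings = 4, k = 21, seed = 7)
#' d <- build_index(sp$strings, k = 21, m = 11, seed = 7)
#' res <- lookup(d, sp$truth$kmer[1:3])
#' access_kmer(d, res$handle)
#' @export
build_index <- function(strings, k, m, mode = c("canonical", "regular"),
                        order = c("random", "lexicographic"), seed = 1,
                        l = 6, r = l + 7) {
  mode <- match.arg(mode)
  order <- match.arg(order)
  stopifnot(is.character(strings), length(strings) >= 1)
  ptr <- cpp_build_index(toupper(strings), as.integer(k), as.integer(m),
                         mode == "canonical", order == "lexicographic",
                         as.numeric(seed), as.integer(l), as.integer(r))
  new_kmer_dict(ptr)
}

new_kmer_dict <- function(ptr) {
  structure(list(ptr = ptr, info = cpp_index_info(ptr)), class = "kmer_dict")
}

#' @export
print.kmer_dict <- function(x, ...) {
  i <- x$info
  sr <- space_report(x)
  cat(sprintf("k-mer dictionary (%s mode, %s order)\n", i$mode, i$order))
  cat(sprintf("  k = %d, m = %d, l = %d, r = %d, seed = %.0f\n",
              i$k, i$m, i$l, i$r, i$seed))
  cat(sprintf("  n = %.0f k-mers in %.0f string(s), N = %.0f bases\n",
              i$n, i$n_strings, i$N))
  cat(sprintf("  M = %.0f minimizers (%.0f singleton), Z = %.0f occurrences, max |loc| = %.0f\n",
              i$M, i$n_singleton, i$Z, i$max_loc))
  cat(sprintf("  skew index: %.0f k-mers in %d partition(s)\n",
              i$alpha, length(i$partition_sizes)))
  cat(sprintf("  space: %.2f bits per k-mer\n", sum(sr$bits) / i$n))
  invisible(x)
}

#' Look up k-mers in a dictionary
#'
#' For each query k-mer the pipeline is: compute the (canonical) minimizer
#' and its in-k-mer position; hash the minimizer to its tag; resolve
#' candidate occurrence positions through the tag's store; verify that the
#' m-mer at the first reachable position actually equals the minimizer
#' (if not, the minimizer never occurs in `S` and the query fails with
#' `found = FALSE`); displace each candidate occurrence `j` to putative
#' k-mer start positions `q = j - pos + 1` (one candidate per strand case
#' in canonical mode), reject any `q` whose window would cross a string
#' boundary (one Elias-Fano successor query on `P`), and compare the
#' packed window with the query.  Regular mode runs the whole pipeline for
#' the forward k-mer first and retries with the reverse complement.
#'
#' Handles are order-preserving: the k-mer starting at position `q` of
#' string `i` has handle `q - (i-1)(k-1)`, so consecutive k-mers of a
#' string have consecutive handles and all handles tile `1..n`.
#'
#' @param dict a `"kmer_dict"`.
#' @param kmers character vector of query k-mers (each of length `k`;
#'   other lengths are an error, not a miss).  K-mers containing
#'   non-ACGT characters are reported as misses.
#' @return data.frame with one row per query: `kmer`, `handle` (NA when
#'   absent), `string_id`, `orientation` (+1 forward, -1 reverse
#'   complement), `position` (absolute start in `S`) and `found` (whether
#'   the query's minimizer occurs in `S` at all).
#' @export
lookup <- function(dict, kmers) {
  stopifnot(inherits(dict, "kmer_dict"), is.character(kmers))
  out <- cpp_lookup(dict$ptr, toupper(kmers))
  data.frame(kmer = kmers, handle = out$handle, string_id = out$string_id,
             orientation = out$orientation, position = out$position,
             found = out$found, stringsAsFactors = FALSE)
}

#' Retrieve the k-mer with a given handle
#'
#' The inverse of [lookup()]: for `h` in `1..n` returns the k-mer whose
#' handle is `h` (the string containing it is recovered from the offsets
#' `P`, then the window is read from the packed sequence).  Any other
#' handle returns the empty string.
#'
#' @param dict a `"kmer_dict"`.
#' @param h numeric vector of handles.
#' @return character vector of k-mers (`""` for out-of-range handles).
#' @export
access_kmer <- function(dict, h) {
  stopifnot(inherits(dict, "kmer_dict"))
  cpp_access(dict$ptr, as.numeric(h))
}

#' Regular displacement
#'
#' Maps a stored minimizer occurrence position `j` and the in-k-mer
#' minimizer position `pos` to the putative k-mer start `q = j - pos + 1`.
#' The caller validates `q` against string boundaries.
#'
#' @param j absolute occurrence position(s).
#' @param pos in-k-mer minimizer position(s).
#' @return numeric vector of candidate start positions.
#' @examples
#' displace_regular(27, 1)  # 27
#' displace_regular(3, 3)   # 1
#' @export
displace_regular <- function(j, pos) {
  stopifnot(all(j >= 1), all(pos >= 1))
  as.numeric(j) - as.numeric(pos) + 1
}

#' Canonical displacements
#'
#' Given a query k-mer `x` and a stored occurrence position `j` of its
#' canonical minimizer, lists the candidate start positions to verify,
#' with the strand each one must be compared on.  When the forward
#' minimizer is strictly smaller than the reverse one (or vice versa) two
#' candidates are produced; when both strands yield the same m-mer, all
#' four.  Candidates that would start before position 1 are dropped.
#'
#' @param x the query k-mer.
#' @param j stored occurrence position.
#' @param scheme a [minimizer_scheme()] with `k = nchar(x)`.
#' @return data.frame with columns `q` and `orientation`.
#' @examples
#' sch <- minimizer_scheme(7, 3, order = "lexicographic")
#' displace_canonical("TTGGCCT", 10, sch)  # candidates 10 and 6
#' @export
displace_canonical <- function(x, j, scheme) {
  stopifnot(inherits(scheme, "minimizer_scheme"), nchar(x) == scheme$k)
  cpp_displace_canonical(toupper(x), as.numeric(j), scheme$m,
                         scheme$order == "lexicographic", scheme$seed)
}

#' Component-wise space report
#'
#' Bit counts of each index component: the 2-bit packed sequence `S`
#' (exactly `2N` bits), the Elias-Fano offsets `P`, the minimizer MPHF
#' `f`, the tag array `T` (`M` words of `ceil(log2 N)+1` bits unless
#' widened), the light and heavy position stores `L` and `H` (together
#' `Z - #singletons` positions of `ceil(log2 N)` bits), the group
#' directory `G` and the skew index.
#'
#' @param dict a `"kmer_dict"`.
#' @return data.frame with columns `component` and `bits`; total bits per
#'   k-mer in attribute `"bits_per_kmer"`.
#' @export
space_report <- function(dict) {
  stopifnot(inherits(dict, "kmer_dict"))
  out <- cpp_space_report(dict$ptr)
  df <- data.frame(component = out$component, bits = out$bits,
                   stringsAsFactors = FALSE)
  attr(df, "bits_per_kmer") <- sum(df$bits) / dict$info$n
  df
}

#' Index statistics
#'
#' @param dict a `"kmer_dict"`.
#' @return list of counts and parameters: `n`, `N`, `M`, `Z`,
#'   `n_super_kmers`, `alpha` (k-mers in the skew index), `beta`
#'   (fraction of non-singleton minimizers), `max_loc`, per-partition
#'   sizes, MPHF bits per key, tag width.
#' @export
index_stats <- function(dict) {
  stopifnot(inherits(dict, "kmer_dict"))
  dict$info
}

#' Save an index to a file
#'
#' The format is versioned, little-endian, with explicit bit widths for
#' every packed array; loading validates magic bytes and a header
#' checksum.  The write is deterministic: the same build parameters and
#' seed produce byte-identical files.
#'
#' @param dict a `"kmer_dict"`.
#' @param path output file.
#' @return invisibly, a list with total `bytes` and per-component byte
#'   counts.
#' @export
save_index <- function(dict, path) {
  stopifnot(inherits(dict, "kmer_dict"))
  invisible(cpp_save_index(dict$ptr, path.expand(path)))
}

#' Load an index from a file
#'
#' @param path file written by [save_index()].
#' @return a `"kmer_dict"`.
#' @export
load_index <- function(path) {
  if (!file.exists(path)) stop("index file '", path, "' does not exist")
  new_kmer_dict(cpp_load_index(path.expand(path)))
}
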
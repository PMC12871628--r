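# Minimizer and canonical-minimizer computation, super-k-mer parsing and
# incremental minimizer maintenance.

#' Define a minimizer sampling scheme
#'
#' A scheme is the triple (k, m, order): the minimizer of a k-mer is its
#' leftmost m-mer that is minimal under a total order on m-mers.  The
#' `"random"` order ranks m-mers by a seeded 64-bit hash of their 2-bit code
#' (the practical choice: it makes minimizers sparse and their occurrence
#' counts skewed but small); the `"lexicographic"` order ranks them by
#' string comparison and is mostly useful for worked examples and
#' debugging.  Ties between distinct m-mers under the random order are
#' broken by the m-mer code, so the order is always total.
#'
#' @param k k-mer length (2--63).
#' @param m minimizer length, `m < k` and `m <= 31`.
#' @param order `"random"` or `"lexicographic"`.
#' @param seed integer seed for the random order (recorded in the index
#'   header; ignored for lexicographic order).
#' @return an object of class `"minimizer_scheme"`.
#' @export
minimizer_scheme <- function(k, m, order = c("random", "lexicographic"), seed = 1) {
  order <- match.arg(order)
  k <- as.integer(k); m <- as.integer(m)
  stopifnot(k >= 2, k <= 63, m >= 1, m < k, m <= 31)
  structure(list(k = k, m = m, order = order, seed = as.numeric(seed)),
            class = "minimizer_scheme")
}

#' @export
print.minimizer_scheme <- function(x, ...) {
  cat(sprintf("minimizer scheme: k = %d, m = %d, %s order (seed %.0f)\n",
              x$k, x$m, x$order, x$seed))
  invisible(x)
}

#' Minimizer of a k-mer
#'
#' Returns the leftmost m-mer of `x` minimal under the scheme's order,
#' together with the 1-based position of that occurrence in `x`.
#'
#' @param x a k-mer (character scalar of length `scheme$k`).
#' @param scheme a [minimizer_scheme()].
#' @return list with elements `mmer` and `pos`.
#' @examples
#' sch <- minimizer_scheme(7, 3, order = "lexicographic")
#' mini("TCAAGTT", sch)  # AAG at position 3
#' @export
mini <- function(x, scheme) {
  stopifnot(inherits(scheme, "minimizer_scheme"), nchar(x) == scheme$k)
  cpp_minimizer(toupper(x), scheme$m, scheme$order == "lexicographic",
                scheme$seed, FALSE)
}

#' Canonical minimizer of a k-mer
#'
#' The canonical minimizer is the order-smaller of the minimizers of `x`
#' and of its reverse complement.  The returned position is expressed on
#' the forward strand of `x`: when the reverse minimizer wins, it is the
#' position in `x` where the *reverse complement* of that m-mer begins,
#' i.e. `rc_position()` applied to its position in `rc(x)`.  When both
#' strands yield the same m-mer the forward position is reported.
#'
#' @inheritParams mini
#' @return list with elements `mmer` and `pos`.
#' @examples
#' sch <- minimizer_scheme(7, 3, order = "lexicographic")
#' cmini("TCAAGTT", sch)  # AAC, which begins (as GTT) at position 5
#' @export
cmini <- function(x, scheme) {
  stopifnot(inherits(scheme, "minimizer_scheme"), nchar(x) == scheme$k)
  cpp_minimizer(toupper(x), scheme$m, scheme$order == "lexicographic",
                scheme$seed, TRUE)
}

#' Position of an m-mer occurrence on the opposite strand
#'
#' If an m-mer begins at position `pos` inside a k-mer, its reverse
#' complement begins at position `k - m - pos + 2` inside the reverse
#' complement of the k-mer.  An involution on `[1 .. k-m+1]`.
#'
#' @param k,m k-mer and m-mer lengths.
#' @param pos 1-based occurrence position (vectorized).
#' @return integer vector of flipped positions.
#' @export
rc_position <- function(k, m, pos) {
  stopifnot(all(pos >= 1), all(pos <= k - m + 1))
  as.integer(k - m - pos + 2)
}

#' Parse a string into super-k-mers
#'
#' A super-k-mer is a maximal run of consecutive k-mers of `s` sharing the
#' same minimizer occurrence.  Boundaries are placed when the *occurrence
#' position* of the chosen minimizer changes (not merely its value), which
#' guarantees that every super-k-mer spans at most `k - m + 1` k-mers and
#' `2k - m` characters, and that each k-mer is reachable from the stored
#' occurrence position of its minimizer.
#'
#' @param s a DNA string of length >= k.
#' @param scheme a [minimizer_scheme()].
#' @param mode `"regular"` (minimizers) or `"canonical"` (canonical
#'   minimizers).
#' @return data.frame with one row per super-k-mer: `start`, `end`
#'   (substring bounds in `s`), `n_kmers`, `minimizer` and `min_pos`
#'   (1-based occurrence position of the minimizer in `s`).
#' @export
parse_super_kmers <- function(s, scheme, mode = c("regular", "canonical")) {
  mode <- match.arg(mode)
  stopifnot(inherits(scheme, "minimizer_scheme"), nchar(s) >= scheme$k)
  cpp_parse_super_kmers(toupper(s), scheme$k, scheme$m,
                        scheme$order == "lexicographic", scheme$seed,
                        mode == "canonical")
}

#' Rolling per-window minimizers of a sequence
#'
#' Computes, for every k-window of `seq`, the minimizer of the window and
#' the minimizer of its reverse complement, maintained incrementally (the
#' stored minimum is reused until it falls out of the window, and the
#' window is re-scanned only then; amortized O(1) per window).  Positions
#' are window-relative: `fwd_pos` in the window, `rc_pos` in the reverse
#' complement of the window.
#'
#' @param seq a DNA string of length >= k.
#' @param scheme a [minimizer_scheme()].
#' @return data.frame with columns `start`, `fwd_mmer`, `fwd_pos`,
#'   `rc_mmer`, `rc_pos`.
#' @export
streaming_minimizers <- function(seq, scheme) {
  stopifnot(inherits(scheme, "minimizer_scheme"), nchar(seq) >= scheme$k)
  cpp_streaming_minimizers(toupper(seq), scheme$k, scheme$m,
                           scheme$order == "lexicographic", scheme$seed)
}
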
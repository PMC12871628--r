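# Elias-Fano representation of sorted integer arrays.

#' Build an Elias-Fano sequence
#'
#' Compresses a sorted (non-decreasing) array of non-negative integers with
#' universe bound `U`.  Each value splits into `l = max(0, floor(log2(U/n)))`
#' low bits, stored fixed-width, and a unary-coded high part; the total core
#' size is at most `n*log2(U/n) + 3n` bits.  Duplicate values are allowed;
#' queries follow the leftmost-index convention.
#'
#' @param values sorted numeric vector of non-negative integers.
#' @param U universe bound, at least `max(values)` (default exactly that).
#' @return an object of class `"ef_sequence"`.
#' @examples
#' e <- ef_build(c(1, 22, 34))
#' ef_access(e, 1:3)
#' ef_successor(e, 2)   # index 2, value 22
#' @export
ef_build <- function(values, U = max(values)) {
  stopifnot(is.numeric(values), length(values) >= 1)
  structure(cpp_ef_build(as.numeric(values), as.numeric(U)), class = "ef_sequence")
}

#' @export
print.ef_sequence <- function(x, ...) {
  sz <- ef_size_bits(x)
  cat(sprintf("Elias-Fano sequence: n = %.0f, U = %.0f, l = %d, %.0f bits\n",
              x$n, x$U, x$l, sz$total_bits))
  invisible(x)
}

#' Access the i-th element of an Elias-Fano sequence
#'
#' @param ef an `"ef_sequence"`.
#' @param i 1-based indices (vectorized); out-of-range is an error.
#' @return numeric vector of values.
#' @export
ef_access <- function(ef, i) {
  stopifnot(inherits(ef, "ef_sequence"))
  cpp_ef_access(ef, as.numeric(i))
}

#' Successor query on an Elias-Fano sequence
#'
#' For each `x`, returns the leftmost element `y >= x` and its index.
#' Requires `x <= A[n]` (the caller guarantees this; larger arguments are
#' an error).  Implemented by locating the high-bits bucket of `x` and
#' scanning forward.
#'
#' @param ef an `"ef_sequence"`.
#' @param x query values (vectorized).
#' @return data.frame with columns `index` and `value`.
#' @export
ef_successor <- function(ef, x) {
  stopifnot(inherits(ef, "ef_sequence"))
  out <- cpp_ef_successor(ef, as.numeric(x))
  data.frame(index = out$index, value = out$value)
}

#' Size of an Elias-Fano sequence in bits
#'
#' The core is `n*l` low bits plus the unary high-part bit vector.  This
#' implementation keeps no auxiliary select structure (selects scan the
#' high words, which is adequate for the array sizes the index stores), so
#' the reported select overhead is zero.
#'
#' @param ef an `"ef_sequence"`.
#' @return list with `low_bits`, `high_bits`, `select_overhead_bits` and
#'   `total_bits`.
#' @export
ef_size_bits <- function(ef) {
  stopifnot(inherits(ef, "ef_sequence"))
  low <- ef$n * ef$l
  list(low_bits = low, high_bits = ef$high_nbits, select_overhead_bits = 0,
       total_bits = low + ef$high_nbits)
}
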
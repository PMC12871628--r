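# Three-type storage of locate sets: tag array, light store, heavy store
# with skew index.

#' Skew-index partition of a heavy locate-set size
#'
#' A heavy minimizer (more than `2^l` occurrences) with locate-set size `z`
#' belongs to partition `i`, the unique value in `[l..r]` with
#' `2^i < z <= 2^(i+1)`, clamped to `r` when `z > 2^(r+1)`.  With the
#' default `r = l + 7` there are at most 8 partitions, so a partition id
#' fits in the 3 tag bits reserved for it.
#'
#' @param z locate-set size(s), each `> 2^l`.
#' @param l,r partition range bounds.
#' @return integer vector of partition ids.
#' @export
skew_partition_of <- function(z, l = 6, r = l + 7) {
  vapply(z, function(zz) cpp_skew_partition_of(as.numeric(zz),
                                               as.integer(l), as.integer(r)),
         integer(1))
}

#' Build a locate-set layout
#'
#' Reorganizes locate sets into three stores selected by a per-minimizer
#' *tag* of `ceil(log2 N) + 1` bits, indexed by a minimal perfect hash of
#' the minimizers:
#' \itemize{
#'   \item singleton (one occurrence): the position lives in the tag
#'     itself; no further store is touched;
#'   \item light (2 to `2^l` occurrences): the set lives in `L`, grouped
#'     by size `z` with a directory `G[z]`; the tag stores `z - 2` and the
#'     index of the set within its size group;
#'   \item heavy (more than `2^l`): the set lives in `H`; the tag stores a
#'     3-bit partition id and the offset of the set in `H`, and a skew
#'     index partition (MPHF `f_i` over the k-mers of those minimizers,
#'     fixed-width vector `V_i` of locate-set indices) resolves a query
#'     k-mer to a single entry `H[o + V_i[f_i(x)]]`.
#' }
#' On inputs so small that a field cannot address its store, the whole tag
#' word widens by the minimum amount and the widening is flagged.
#'
#' This standalone constructor exists for inspection and testing; inside a
#' dictionary the same layout is built by [build_index()].
#'
#' @param occ named list: minimizer (an m-mer string) -> sorted vector of
#'   its absolute occurrence positions in `[1..N]`.
#' @param heavy_kmers named list for minimizers with more than `2^l`
#'   occurrences: each element is `list(kmers =, loc_index =)`, the k-mers
#'   of that minimizer and the 1-based index of each k-mer's occurrence
#'   inside the minimizer's sorted locate set.
#' @param l light/heavy threshold exponent (sets of size <= `2^l` are
#'   light); default 6.
#' @param r top skew partition; default `l + 7` so the partition id fits
#'   3 bits.
#' @param N length of the underlying concatenation (positions are
#'   validated against it).
#' @param seed seed for the internal MPHFs.
#' @param canonical identify m-mers/k-mers with their reverse complements.
#' @return an object of class `"locate_layout"`.
#' @export
build_layout <- function(occ, heavy_kmers = list(), l = 6, r = l + 7, N,
                         seed = 1, canonical = FALSE) {
  stopifnot(is.list(occ), length(occ) >= 1, !is.null(names(occ)))
  out <- cpp_build_layout(occ, heavy_kmers, as.integer(l), as.integer(r),
                          as.numeric(N), as.numeric(seed), isTRUE(canonical))
  structure(out, class = "locate_layout")
}

#' @export
print.locate_layout <- function(x, ...) {
  cat(sprintf(paste0("locate layout: M = %.0f minimizers (%.0f singleton), ",
                     "L = %.0f, H = %.0f entries, %d skew partition(s), ",
                     "tag width %d%s\n"),
              x$M, x$n_singleton, x$L_entries, x$H_entries, x$n_partitions,
              x$tag_width, if (isTRUE(x$widened)) " (widened)" else ""))
  invisible(x)
}

#' Resolve a minimizer through a layout
#'
#' Follows the tag dispatch for `mmer` and returns the reachable candidate
#' positions together with instrumented probe counts (entries read from
#' `L`, `H`, `V_i` and `G`).  For a heavy minimizer the k-mer must be
#' supplied, since the skew index returns one position per k-mer; without
#' it no candidate is produced.
#'
#' @param layout a `"locate_layout"`.
#' @param mmer the minimizer (m-mer string).
#' @param kmer the query k-mer (required on the heavy path).
#' @return list with `type` (`"singleton"`, `"light"`, `"heavy"`),
#'   `tag_slot`, `candidates` (absolute positions) and `probes`.
#' @export
layout_locate <- function(layout, mmer, kmer = NULL) {
  stopifnot(inherits(layout, "locate_layout"))
  cpp_layout_locate(layout$blob, toupper(mmer),
                    if (is.null(kmer)) "" else toupper(kmer))
}
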
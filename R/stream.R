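# Streaming lookup over reads with budget-based extension.

#' Streaming lookup of all k-mers of a set of reads
#'
#' Answers `lookup()` for every k-window of every read while carrying the
#' state of the last match across windows.  Per window, in order:
#' \enumerate{
#'   \item the window's minimizers (both strands) are updated
#'     incrementally;
#'   \item if a previous match exists and the budget is positive, an
#'     *extension* is attempted: the window is compared directly against
#'     the next (orientation +1) or previous (orientation -1) position of
#'     the matched string -- even when the minimizer changed;
#'   \item otherwise, if the previous window proved its minimizer absent
#'     from the index and the current window has the same minimizers, the
#'     window is reported absent without any lookup;
#'   \item otherwise the window is *seeded*: a full lookup runs and the
#'     budget is reset.
#' }
#' The output is identical to calling [lookup()] on every window
#' independently (forcing `budget = 0` disables extensions and degenerates
#' to exactly that); the point of the state is speed, not a different
#' answer.  Windows containing non-ACGT characters are reported invalid
#' and restart the state.
#'
#' @param dict a `"kmer_dict"`.
#' @param reads character vector of reads, each of length >= k.
#' @param budget maximum number of consecutive extensions after each seed
#'   (default 32).
#' @return data.frame with one row per window: `read`, `window`, `handle`,
#'   `string_id`, `orientation`, `position`, `found`, `valid` and `method`
#'   (`"seed"`, `"extend"`, `"skip"`, `"invalid"`).  Aggregate counters
#'   are in attribute `"stats"`; see [stream_stats()].
#' @export
stream_lookup <- function(dict, reads, budget = 32) {
  stopifnot(inherits(dict, "kmer_dict"), is.character(reads), budget >= 0)
  out <- cpp_stream_lookup(dict$ptr, toupper(reads), as.numeric(budget))
  df <- data.frame(read = out$read, window = out$window, handle = out$handle,
                   string_id = out$string_id, orientation = out$orientation,
                   position = out$position, found = out$found,
                   valid = out$valid,
                   method = c("seed", "extend", "skip", "invalid")[out$method + 1L],
                   stringsAsFactors = FALSE)
  attr(df, "stats") <- out$stats
  df
}

#' Aggregate statistics of a streaming run
#'
#' @param run the data.frame returned by [stream_lookup()].
#' @return list with `windows`, `positive`, `extensions`, `seeds`,
#'   `skipped`, `invalid` and `extension_rate` (= extensions / windows).
#'   Extensions, seeds, skips and invalid windows partition the total.
#' @export
stream_stats <- function(run) {
  st <- attr(run, "stats")
  if (is.null(st)) stop("not a stream_lookup() result (missing stats attribute)")
  st
}
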
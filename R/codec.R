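# DNA alphabet handling, 2-bit packing and the SPSS concatenation.

#' Encode a DNA k-mer as a 2-bit integer code
#'
#' Each base maps to two bits (A=0, C=1, G=2, T=3) and the base at position 1
#' occupies the least significant pair, so the code of a k-mer equals
#' \eqn{\sum_p d_p 4^{p-1}} where \eqn{d_p} is the digit of the base at
#' position p.  Because codes reach \eqn{4^{63}}, far beyond the exact
#' integer range of a double, codes are returned as decimal strings.
#'
#' @param s character vector of k-mers over \{A,C,G,T\} (case-insensitive).
#' @return character vector of decimal integer codes.
#' @examples
#' encode_kmer("AAAAAAA")       # "0"
#' decode_kmer(encode_kmer("ACGT"), 4)
#' @seealso [decode_kmer()], [reverse_complement()]
#' @export
encode_kmer <- function(s) {
  stopifnot(is.character(s))
  cpp_encode_kmers(toupper(s))
}

#' Decode a 2-bit integer code back into a k-mer
#'
#' @param code character (or numeric) vector of codes as produced by
#'   [encode_kmer()].
#' @param k k-mer length (1--63).
#' @return character vector of k-mers.
#' @export
decode_kmer <- function(code, k) {
  if (is.numeric(code)) {
    stopifnot(all(code >= 0), all(code == floor(code)))
    code <- sprintf("%.0f", code)
  }
  cpp_decode_kmers(as.character(code), as.integer(k))
}

#' Reverse complement of DNA strings
#'
#' Characters appear in reverse order and complemented (A<->T, C<->G).
#' An involution: `reverse_complement(reverse_complement(x))` equals `x`.
#'
#' @param s character vector of DNA strings.
#' @return character vector of the same lengths.
#' @examples
#' reverse_complement("AACTTGA")  # "TCAAGTT"
#' @export
reverse_complement <- function(s) {
  stopifnot(is.character(s))
  cpp_revcomp(toupper(s))
}

#' Pack an SPSS into a 2-bit concatenation
#'
#' Concatenates the strings in input order into `S[1..N]` (2 bits per base)
#' and records the start position `p_i` of each string, with the sentinel
#' `p_{|S|+1} = N + 1`.  Every string must have length at least `k` and no
#' k-mer may occur twice across strings; with `canonical = TRUE` the
#' disjointness check identifies a k-mer with its reverse complement.
#'
#' @param strings character vector of DNA strings (each of length >= k).
#' @param k k-mer length (1--63).
#' @param canonical compare k-mers up to reverse complement in the
#'   duplicate check (default TRUE, the SPSS contract used by the
#'   canonical index modality; it is the stricter of the two checks).
#' @return an object of class `"spss"`: a list with elements `packed` (raw),
#'   `N`, `P` (start positions including the sentinel), `k`, `n_strings`,
#'   `n_kmers`.
#' @examples
#' sp <- pack_spss(c("TCAAGTTACTGGACTTTGACC", "GCACGGTATCAG"), k = 7)
#' sp$N          # 33
#' sp$P          # 1 22 34
#' sp$n_kmers    # 21
#' @export
pack_spss <- function(strings, k, canonical = TRUE) {
  stopifnot(is.character(strings), length(strings) >= 1)
  out <- cpp_pack_spss(toupper(strings), as.integer(k), isTRUE(canonical))
  structure(out, class = "spss")
}

#' @export
print.spss <- function(x, ...) {
  cat(sprintf("SPSS: %d string(s), N = %.0f bases, %.0f k-mers (k = %d)\n",
              x$n_strings, x$N, x$n_kmers, x$k))
  invisible(x)
}

#' Extract a substring from a packed SPSS
#'
#' Returns `S[q..q+w)` decoded back to characters; 1-based, half-open.
#' Out-of-range windows are an error (distinct from a failed lookup).
#'
#' @param spss an `"spss"` object from [pack_spss()].
#' @param q 1-based start position.
#' @param w width.
#' @return a character scalar of length `w`.
#' @export
spss_extract <- function(spss, q, w) {
  stopifnot(inherits(spss, "spss"))
  cpp_spss_extract(spss$packed, spss$N, q, w)
}

#' Read an SPSS from a FASTA file
#'
#' Multi-line records are allowed; headers are kept only as names for
#' diagnostics.
#'
#' @param path FASTA file (optionally gzip-compressed).
#' @return named character vector of sequences.
#' @export
read_spss_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  stats::setNames(as.character(x), names(x))
}

#' Write strings to a FASTA file
#'
#' @param strings character vector of DNA strings.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spss_fasta <- function(strings, path) {
  x <- Biostrings::DNAStringSet(strings)
  names(x) <- if (is.null(names(strings))) paste0("s", seq_along(strings)) else names(strings)
  Biostrings::writeXStringSet(x, path, format = "fasta")
  invisible(path)
}

#' Read a FASTQ read set
#'
#' gzip-compressed files are decompressed on the fly by the underlying
#' parser; the decompressed file is never materialized.
#'
#' @param path FASTQ file, plain or `.gz`.
#' @return character vector of reads.
#' @export
read_reads_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  unname(as.character(x))
}

#' Write reads to a FASTQ file
#'
#' @param reads character vector of reads.
#' @param path output path; a `.gz` suffix selects gzip compression.
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads)
  names(x) <- paste0("r", seq_along(reads))
  q <- Biostrings::BStringSet(strrep("I", nchar(reads)))
  names(q) <- names(x)
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}
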
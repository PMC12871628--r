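# kmerdict

An order-preserving, minimizer-based dictionary over the k-mers of a
spectrum-preserving string set (SPSS), for R — with a compiled core.

## What problem this solves

Tools that work on de Bruijn graphs (abundance tracking, colored-graph
pseudoalignment, positional indexes) need an associative structure over
the *n* distinct k-mers of a genome or pangenome: `LOOKUP(x)` returns a
handle in `[1..n]` or ⊥, and `ACCESS(h)` returns the k-mer back. kmerdict
indexes an SPSS — strings of length ≥ k (unitigs/eulertigs from an
upstream compactor) that contain every k-mer exactly once, up to reverse
complement — and assigns the k-mer starting at position *q* of string *i*
the handle

    h = q − (i − 1)(k − 1)

so handles tile `[1..n]` exactly and consecutive, (k−1)-overlapping
k-mers get consecutive handles. That order preservation is what makes
per-k-mer satellite data (counts, color sets) compress well downstream.

The structure is *sparse and skew hashing*:

* the 2-bit packed concatenation `S[1..N]` with Elias-Fano coded string
  offsets `P`;
* a minimal perfect hash function `f` over the **minimizers** of the
  k-mers (sparse: ~`2/(k−m+2)` of positions are sampled);
* per minimizer φ, its locate set `loc(φ) = { pos(x,S) + pos(φ,x) − 1 }` —
  sampled occurrence positions, so a stored occurrence `j` *displaces*
  to the unique candidate start `q = j − pos(φ,x) + 1` (2–4 strand-aware
  candidates in canonical mode) with no linear search;
* a three-type tag layout: singleton minimizers answer from the tag
  alone, light ones from a size-grouped array `L`, and heavy
  (highly-repetitive) ones through a skew index — an MPHF `f_i` per
  size class plus a fixed-width vector `V_i` picking the single entry
  `H[o + V_i[f_i(x)]]` to probe;
* a streaming mode that answers all windows of a read, extending the
  previous match while a budget lasts and skipping windows whose
  minimizer was just proven absent.

Both strands are supported, either by retry (`mode = "regular"`) or via
canonical minimizers (`mode = "canonical"`, the default).

## A worked example

```r
library(kmerdict)

sp <- gen_spss(100000, n_strings = 50, k = 31, seed = 1)  # synthetic SPSS
d  <- build_index(sp$strings, k = 31, m = 21, mode = "canonical", seed = 1)
d
#> k-mer dictionary (canonical mode, random order)
#>   k = 31, m = 21, l = 6, r = 13, seed = 1
#>   n = 98500 k-mers in 50 string(s), N = 100000 bases
#>   M = 16503 minimizers (16503 singleton), Z = 16503 occurrences, max |loc| = 1
#>   skew index: 0 k-mers in 0 partition(s)
#>   space: 5.73 bits per k-mer

lookup(d, c(sp$truth$kmer[5000],
            reverse_complement(sp$truth$kmer[5001]),
            strrep("A", 31)))[, -1]
#>   handle string_id orientation position found
#> 1   5000         3           1     5060  TRUE
#> 2   5001         3          -1     5061  TRUE
#> 3     NA        NA          NA       NA FALSE

access_kmer(d, 5000)
#> [1] "AACGGCCACCACCTAGGGTTCACCCTCTAAC"
```

The two indexed queries land on consecutive positions of string 3 and so
get consecutive handles (5000, 5001); the second was queried as its
reverse complement, hence orientation −1. The all-A k-mer is absent:
`handle` is NA and `found = FALSE` records that even its minimizer never
occurs in `S`.

Streaming a 1000-read, 1%-error workload over the same index:

```r
rs <- gen_reads(sp$strings, 1000, 150, sub_rate = 0.01, seed = 2)
unlist(stream_stats(stream_lookup(d, rs$reads)))[c(1:5, 7)]
#>    windows   positive extensions      seeds    skipped extension_rate
#>     120000      94210      90602      16567      12831      0.7550167
```

75% of windows are answered by a single packed-string comparison
(extension); the rest seed a full lookup or are skipped because the
previous window proved their minimizer absent. The output is guaranteed
identical to per-window `lookup()`.

A shell entry point covering `build`, `query` (single k-mer or
FASTQ/gzip streaming), `access`, `stats` and `gen` is installed at
`inst/cli/kmerdict`:

```sh
Rscript inst/cli/kmerdict build -i spss.fa -k 31 -m 21 --mode canonical -o index.kdx
Rscript inst/cli/kmerdict query -x index.kdx -q reads.fastq.gz --streaming
```

See the vignette (`vignettes/kmer-dictionary-methods.Rmd`) for the
displacement case analysis, the tag bit layout, and every design
decision with its rationale.

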
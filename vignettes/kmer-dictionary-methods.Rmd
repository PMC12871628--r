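---
title: "Inside kmerdict: sparse and skew hashing for k-mer dictionaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inside kmerdict: sparse and skew hashing for k-mer dictionaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmerdict)
```

## The problem

Many sequence-analysis pipelines need an *associative* structure over the
n distinct k-mers of a genome or pangenome: given a k-mer, return a stable
integer identifier (or "not present"), and given an identifier, return the
k-mer. kmerdict implements such a dictionary over a
*spectrum-preserving string set* (SPSS): a set of strings
$\mathcal{S} = \{s_i\}$, each of length $\ge k$, that together spell every
k-mer of the input exactly once (up to reverse complement). Unitigs and
eulertigs produced by de Bruijn graph compactors are SPSSs; the package
does not build them, it indexes them.

Two properties drive the design:

* **Minimality and order preservation.** Every indexed k-mer receives a
  handle in exactly $[1..n]$, and the k-mer starting at position $q$ of
  string $i$ gets $h = q - (i-1)(k-1)$, so consecutive (overlapping)
  k-mers of a string get consecutive handles. Satellite data such as
  abundances or colour classes indexed by handle then inherit the
  locality of the underlying sequence.
* **Sparse hashing.** Hashing every k-mer is wasteful; instead a minimal
  perfect hash function (MPHF) is built over the *minimizers* of the
  k-mers. Minimizers are sparse — about $2/(k-m+2)$ of positions are
  sampled — so the per-k-mer cost of the hash tables is a fraction of a
  bit.

## Anatomy of the index

The dictionary stores:

1. the concatenation $S[1..N]$ of the SPSS, 2 bits per base, with string
   start offsets $P$ in an Elias-Fano sequence;
2. an MPHF $f$ over the set $\mathcal{M}$ of distinct minimizers;
3. for every minimizer $\phi$ its *locate set*
   $\mathrm{loc}(\phi) = \{\,\mathrm{pos}(x,S) + \mathrm{pos}(\phi,x) - 1\,\}$:
   the sorted distinct absolute positions where $\phi$ was sampled, one
   entry per super-k-mer. Storing occurrence positions rather than
   super-k-mer starts is what makes lookup search-free: a stored
   occurrence $j$ maps to the unique putative k-mer start
   $q = j - \mathrm{pos}(\phi, x) + 1$;
4. a *skew index* for the few minimizers with very large locate sets.

Locate sets are laid out by type, selected by a per-minimizer *tag* of
$\lceil\log_2 N\rceil + 1$ bits indexed by $f$:

* **singleton** (one occurrence): the position is in the tag; zero extra
  memory reads;
* **light** ($2 \le z \le 2^l$): sets live in an array `L` grouped by
  size, with a directory `G`; at most $2^l$ entries are scanned;
* **heavy** ($z > 2^l$): sets live in `H`; the tag carries a 3-bit
  partition id and the offset $o$ of the set. Partition $i \in [l..r]$
  holds the k-mers of minimizers with $2^i < z \le \min(2^{i+1},
  z_{\max})$; an MPHF $f_i$ over those k-mers and a width-$(i{+}1)$
  vector $V_i$ yield the single entry $H[o + V_i[f_i(x)]]$ to probe.

With the default $r = l + 7$ there are at most 8 partitions, so the id
fits the 3 tag bits.

## Canonical modality and displacements

DNA is double-stranded, so a query must match either the k-mer or its
reverse complement. In the *regular* modality the forward k-mer runs the
whole pipeline first and the reverse complement is retried on failure. In
the *canonical* modality (the default) the sampling uses the canonical
minimizer $\min\{\mathrm{MINI}(x), \mathrm{MINI}(\bar{x})\}$, so both
strands share one locate set and a single pass suffices.

The canonical position convention is the crux. The position of the
canonical minimizer in $x$ is the position of $\mathrm{MINI}(x)$ when the
forward strand wins (ties included), and otherwise the position in $x$
where the *complement* of $\mathrm{MINI}(\bar{x})$ begins — by the strand
flip identity $\mathrm{pos}(\bar\phi, \bar{x}) = k - m -
\mathrm{pos}(\phi, x) + 2$. At query time we cannot know which strand of
the query is stored, so a stored occurrence $j$ yields two candidate
starts (four when both strands have the same minimizer string), each
compared on its own strand; candidates falling before position 1 or
across a string boundary are dropped. `displace_canonical()` exposes this
case analysis directly and the package's tests pin it to hand-worked
examples.

## Choices the design left open

These are the decisions a reimplementation has to make; the package fixes
them as follows.

* **Super-k-mer boundaries.** A super-k-mer ends when the minimizer's
  *occurrence position* changes, not merely its value. The stricter rule
  keeps every k-mer reachable from its stored occurrence and preserves
  the $\le k-m+1$ k-mer / $\le 2k-m$ character bounds.
* **Orders and ties.** An order on m-mers is either lexicographic or a
  seeded 64-bit hash of the m-mer code; comparisons use the pair (hash,
  code), so the order is total and two m-mers compare equal only when
  they are the same string. Forward-strand scans keep the leftmost
  minimal occurrence; reverse-strand scans keep the occurrence that is
  leftmost *on that strand* (rightmost in forward coordinates).
* **A sound `found` flag.** Lookup reports whether the query's minimizer
  occurs in `S` at all, by comparing the m-mer at the first reachable
  locate position with the minimizer — an MPHF cannot reject foreign keys
  by itself. On the heavy path the single skew probe may land on a wrong
  entry for a k-mer that is not in the index; only in that failure case
  is one extra probe at the set's first entry spent so that `found` never
  reports a present minimizer as absent. The streaming negative-skip rule
  relies on this soundness; successful lookups still pay exactly one `H`
  and one `V` probe.
* **Tag capacity on tiny inputs.** When $N$ is so small that a light
  group index or heavy offset cannot fit its tag field, the whole tag
  word widens by the minimum amount and the widening is recorded. Real
  inputs never trigger this; toy examples do.
* **Widths.** Positions are stored as value$-1$ in
  $\lceil\log_2 N\rceil$ bits. $V_i$ uses $i+1$ bits, or
  $\lceil\log_2 z_{\max}\rceil$ in the top partition. m is capped at 31
  so an m-mer code fits one 64-bit word (practical minimizer lengths are
  19–25); k is capped at 63 (two bits per base in a 126-bit code).
* **Elias-Fano.** $\ell = \max(0, \lfloor\log_2(U/n)\rfloor)$; successor
  locates the high-bits bucket and scans forward. No select acceleration
  structure is kept: the arrays it stores (string offsets) are small, so
  the reported select overhead is zero and the core obeys
  $n\log_2(U/n) + 3n$ bits.
* **MPHF.** Bucket placement at full load: keys hash to ~$M/4$ buckets;
  buckets are placed largest-first by searching per-bucket pilots until
  all keys land on free slots of a size-$M$ table; pilots are stored
  fixed-width. Construction retries with derived seeds on a pilot-budget
  overflow or a (vanishingly rare) 64-bit hash collision, and measures
  3–5 bits per key at the scales the package targets — comfortably above
  the $\log_2 e \approx 1.443$ floor, traded for construction simplicity
  and two-hash evaluation.

## Streaming lookup

`stream_lookup()` answers every k-window of a read while carrying the
last match: handle, string id, orientation, position, the `found` flag
and the window minimizers, plus a *budget*. While the budget is positive
an extension — one packed-sequence comparison at $q \pm 1$, bounds-checked
against the string — is attempted even when the minimizer changed; a
success costs no hashing at all. When extension fails, a window whose
minimizers equal the previous window's is answered "absent" without any
lookup if that window already proved the minimizer absent; otherwise a
full lookup re-seeds the state and resets the budget.

The budget default is 32: extensions are so much cheaper than seeds that
the cap only bounds pathological comparison runs on adversarial reads; it
is exposed as a parameter (and CLI flag) for experimentation. Setting it
to 0 degenerates to per-window lookup, which the test suite uses to pin
exact output equivalence. The equivalence guarantee assumes no k-mer and
its reverse complement are both indexed — true for any
canonically-distinct SPSS, which the generator produces and the builder
verifies in canonical mode.

Rolling minimizers are maintained by the re-scan method: the current
minimum is reused until it falls out of the window and only then is the
window re-scanned, giving amortized O(1) work per window for both
strands.

## The synthetic generator, and what passing tests do not show

`gen_spss()` emulates the *contract* of compacted de Bruijn graph output:
strings of length $\ge k$ with globally distinct canonical k-mers,
i.i.d. uniform bases, enforced during generation by checking each
appended base against the emitted k-mer set. `gen_reads()` samples
windows (weighted by string length), optionally reverse-complements them,
applies substitutions — a "substitution" draws a uniform base, so one in
four leaves the base unchanged and a nominal 1% rate changes 0.75% of
bases, which at k=31 leaves about 79% of windows intact, a high-hit
workload — and mixes in fully random foreign reads.

Uniform random sequence is the friendliest case for minimizer schemes: it
matches the density expectation $2/(k-m+2)(N-m+1)$ and produces mild
locate-set skew. Real pangenomes contain low-complexity repeats that
concentrate occurrences on few minimizers; the skew index exists for
exactly that case, and the tests exercise it by shortening m (m = 5–7
over tens of kilobases produces locate sets in the hundreds) rather than
by modelling biological repeat structure. Absolute space figures
(bits/k-mer) on synthetic data are likewise not predictive of real
genomes, where N/n ratios and minimizer sparsity differ; the space
*accounting* identities the tests assert are exact regardless of input.

Problem sizes used by the test suite were chosen to exercise every code
path at desk scale: 100 kb SPSSs over 50 strings for the bijection,
negative-soundness and streaming-equivalence suites (≈ 98,500 k-mers,
1.2 M streamed windows), $10^5$ keys for MPHF bijections, $10^5$-base
strings for density checks. Each suite completes in seconds; the whole
suite in about two minutes.

## Limitations

* The dictionary is static: no insertions or deletions.
* No payloads (abundances, colours) are stored; handles are designed to
  index external payload arrays.
* k ≤ 63, m ≤ 31, and the minimizer scheme is the classic
  window-minimum; alternative samplers (mod-minimizers, syncmers,
  sequence-specific orders) are out of scope.
* Construction is single-threaded and in-memory, sized for inputs up to
  tens of megabases; the on-disk format is nonetheless versioned and
  byte-deterministic given the build seed.
* The cache-miss cost model that motivates the three-type layout (counting
  line transfers per query) is documented here but not instrumented at
  runtime; the probe-count contract (entries read per store) is what the
  implementation exposes and tests.

## A small worked session

```{r example}
sp <- gen_spss(20000, n_strings = 10, k = 31, seed = 42)
d <- build_index(sp$strings, k = 31, m = 15, seed = 42)
d

res <- lookup(d, sp$truth$kmer[101:103])
res[, c("handle", "string_id", "orientation", "position", "found")]

access_kmer(d, res$handle[1])

rs <- gen_reads(sp$strings, 500, 150, sub_rate = 0.01, seed = 1)
st <- stream_stats(stream_lookup(d, rs$reads))
unlist(st)
```
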
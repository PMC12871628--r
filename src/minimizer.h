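#ifndef KMERDICT_MINIMIZER_H
#define KMERDICT_MINIMIZER_H

// Minimizer and canonical-minimizer computation, occurrence-position algebra,
// super-k-mer parsing and incremental (rolling) minimizer maintenance.
//
// An order O over m-mers is either "lexicographic" (numeric order of BE
// codes) or "random" (a seeded 64-bit hash of the BE code).  Comparisons use
// the pair (O(mu), code) so that the order is total and two m-mers compare
// equal only when they are the same string.

#include "kmer.h"

namespace kmerdict {

struct MinOrder {
    bool lex = true;
    u64 seed = 0;
    int m = 0;
    u64 key(u64 code) const { return lex ? code : hash_u64(code, seed); }
    // strict order: a before b
    bool less(u64 a, u64 b) const {
        u64 ka = key(a), kb = key(b);
        return ka < kb || (ka == kb && a < b);
    }
};

struct MinimizerHit {
    u64 mmer = 0; // BE code
    int pos = 0;  // 1-based start of the chosen occurrence
};

// Observation-style position flip between strands.
inline int rc_position(int k, int m, int pos) { return k - m - pos + 2; }

inline u64 mmer_at(u128 x, int k, int m, int p) { // m-mer of x starting at p
    return (u64)((x >> (2 * (k - p - m + 1))) & ((((u128)1) << (2 * m)) - 1));
}

// Leftmost O-minimal m-mer of a k-mer given as a BE code.
inline MinimizerHit mini_code(u128 x, int k, int m, const MinOrder& O) {
    MinimizerHit best;
    best.pos = 0;
    for (int p = 1; p <= k - m + 1; ++p) {
        u64 mm = mmer_at(x, k, m, p);
        if (best.pos == 0 || O.less(mm, best.mmer)) { best.mmer = mm; best.pos = p; }
    }
    return best;
}

// Canonical minimizer: value is the O-smaller of MINI(x) and MINI(rc(x)); the
// position is expressed on the forward strand of x (where the value itself,
// or its reverse complement, begins).
struct CanonicalHit {
    u64 mmer = 0;     // canonical value (BE code)
    int pos = 0;      // forward-strand position in x
    int cmp = 0;      // -1: MINI(x) < MINI(rc x); +1: >; 0: same m-mer
    MinimizerHit fwd; // MINI(x)
    MinimizerHit rev; // MINI(rc(x)), position within rc(x)
};

inline CanonicalHit cmini_code(u128 x, u128 xr, int k, int m, const MinOrder& O) {
    CanonicalHit h;
    h.fwd = mini_code(x, k, m, O);
    h.rev = mini_code(xr, k, m, O);
    if (O.less(h.fwd.mmer, h.rev.mmer)) h.cmp = -1;
    else if (O.less(h.rev.mmer, h.fwd.mmer)) h.cmp = +1;
    else h.cmp = 0;
    if (h.cmp <= 0) { // MINI(x) <= MINI(rc(x)): forward wins (ties included)
        h.mmer = h.fwd.mmer;
        h.pos = h.fwd.pos;
    } else {          // the reverse minimizer occurs in x as its complement
        h.mmer = h.rev.mmer;
        h.pos = rc_position(k, m, h.rev.pos);
    }
    return h;
}

// One candidate displacement: start q = j - d + 1, compared on strand o.
struct Disp { int d; int orient; };

// Canonical displacement function d(x, j): 2 candidates in the strict cases,
// 4 when MINI(x) equals MINI(rc(x)).
inline void canonical_disps(const CanonicalHit& h, int k, int m, std::vector<Disp>& out) {
    out.clear();
    if (h.cmp < 0) {
        out.push_back({h.fwd.pos, +1});
        out.push_back({rc_position(k, m, h.fwd.pos), -1});
    } else if (h.cmp > 0) {
        out.push_back({h.rev.pos, -1});
        out.push_back({rc_position(k, m, h.rev.pos), +1});
    } else {
        out.push_back({h.fwd.pos, +1});
        out.push_back({rc_position(k, m, h.fwd.pos), -1});
        out.push_back({h.rev.pos, -1});
        out.push_back({rc_position(k, m, h.rev.pos), +1});
    }
}

// A super-k-mer: a maximal run of consecutive k-mers of one string sharing
// the same minimizer occurrence (value and absolute position).
struct SuperKmer {
    u64 value = 0;   // minimizer key (canonical value in canonical mode)
    u64 j = 0;       // absolute occurrence position (string-local or in S)
    u64 win_start = 0;
    u64 n_kmers = 0;
};

// Parse the k-mers of s (BE codes streamed from a callback) into super-k-mer
// runs.  `get_window(w)` must return the BE code of the k-mer starting at w.
template <typename GetWin>
inline void parse_runs(u64 n_windows, int k, int m, const MinOrder& O, bool canonical,
                       GetWin get_window, std::vector<SuperKmer>& out) {
    out.clear();
    for (u64 w = 1; w <= n_windows; ++w) {
        u128 x = get_window(w);
        u64 value; int pos;
        if (canonical) {
            CanonicalHit h = cmini_code(x, rc_be(x, k), k, m, O);
            value = h.mmer; pos = h.pos;
        } else {
            MinimizerHit h = mini_code(x, k, m, O);
            value = h.mmer; pos = h.pos;
        }
        u64 j = w + (u64)pos - 1;
        if (!out.empty() && out.back().j == j && out.back().value == value) {
            out.back().n_kmers++;
        } else {
            out.push_back({value, j, w, 1});
        }
    }
}

// Rolling minimizer state for one strand over a sliding window of k-m+1
// m-mer positions ("re-scan" maintenance: amortized O(1) per shift).
// For the forward strand ties keep the leftmost position; for the reverse
// strand ties keep the rightmost forward position (leftmost on that strand).
struct RollingMin {
    const MinOrder* O = nullptr;
    bool prefer_right = false;
    u64 best_code = 0;
    long best_pos = -1; // absolute position; -1 = empty

    void reset() { best_pos = -1; }
    bool better(u64 code, long pos) const {
        if (best_pos < 0) return true;
        if (O->less(code, best_code)) return true;
        if (prefer_right && code == best_code && pos > best_pos) return true;
        return false;
    }
    void offer(u64 code, long pos) {
        if (better(code, pos)) { best_code = code; best_pos = pos; }
    }
};

} // namespace kmerdict

#endif
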
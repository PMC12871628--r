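#ifndef KMERDICT_EF_H
#define KMERDICT_EF_H

// Elias-Fano representation of a sorted (non-decreasing) integer array with
// ACCESS(i) and SUCCESSOR(x).  Each value splits into l low bits, stored in a
// fixed-width array, and a high part coded in unary in a bit vector.  With
// l = floor(log2(U/n)) the total size is at most n*log2(U/n) + 3n bits.

#include "common.h"

namespace kmerdict {

struct EliasFano {
    u64 n = 0, U = 0;
    int l = 0;
    IntVec low;      // n entries of width l (absent when l == 0)
    BitVec high;     // n ones among (U >> l) + 1 + n bits

    void build(const std::vector<u64>& A, u64 U_) {
        n = A.size();
        if (n == 0) throw std::runtime_error("Elias-Fano input must be non-empty");
        for (u64 i = 1; i < n; ++i)
            if (A[i] < A[i - 1]) throw std::runtime_error("Elias-Fano input must be sorted");
        if (A[n - 1] > U_) throw std::runtime_error("Elias-Fano universe smaller than last element");
        U = U_;
        l = 0;
        while (l < 63 && (n << (l + 1)) <= U && ((n << (l + 1)) >> (l + 1)) == n) ++l;
        if (l > 0) {
            low.resize(n, l);
            for (u64 i = 0; i < n; ++i) low.set(i, A[i] & ((1ULL << l) - 1));
        } else {
            low = IntVec();
        }
        high.resize((U >> l) + n + 1);
        for (u64 i = 0; i < n; ++i) high.set((A[i] >> l) + i);
    }

    u64 access(u64 i) const { // 1-based
        if (i < 1 || i > n) throw std::runtime_error("Elias-Fano access out of range");
        u64 p = select1(i - 1);
        u64 hi = p - (i - 1);
        u64 lo = (l > 0) ? low.get(i - 1) : 0;
        return (hi << l) | lo;
    }

    // Leftmost (index, value) with value >= x; requires x <= A[n].
    std::pair<u64, u64> successor(u64 x) const {
        u64 hx = x >> l;
        // position of the hx-th zero: elements before it have high part < hx
        u64 i = (hx == 0) ? 0 : ones_before_zero(hx);
        u64 p = (hx == 0) ? 0 : (select0(hx - 1) + 1);
        while (p < high.nbits) {
            if (high.get(p)) {
                u64 hi = p - i;
                u64 lo = (l > 0) ? low.get(i) : 0;
                u64 v = (hi << l) | lo;
                if (v >= x) return {i + 1, v};
                ++i;
            }
            ++p;
        }
        throw std::runtime_error("successor: argument exceeds last element");
    }

    u64 size_bits() const { return (u64)l * n + high.nbits; }

    void save(Writer& w) const {
        w.put_u64(n); w.put_u64(U); w.put_u64((u64)l);
        w.put_words(l > 0 ? low.words : std::vector<u64>());
        w.put_u64(high.nbits);
        w.put_words(high.words);
    }
    void load(Reader& r) {
        n = r.get_u64(); U = r.get_u64(); l = (int)r.get_u64();
        std::vector<u64> lw; r.get_words(lw);
        if (l > 0) { low.resize(n, l); std::copy(lw.begin(), lw.end(), low.words.begin()); }
        u64 nb = r.get_u64();
        high.resize(nb);
        r.get_words(high.words);
        high.nbits = nb;
    }

  private:
    u64 select1(u64 rank) const { // position of the (rank+1)-th one
        u64 seen = 0;
        for (u64 wi = 0; wi < high.words.size(); ++wi) {
            int c = __builtin_popcountll(high.words[wi]);
            if (seen + (u64)c > rank) {
                u64 w = high.words[wi];
                u64 need = rank - seen;
                for (int b = 0; b < 64; ++b) {
                    if ((w >> b) & 1) {
                        if (need == 0) return wi * 64 + (u64)b;
                        --need;
                    }
                }
            }
            seen += (u64)c;
        }
        throw std::runtime_error("select1 out of range");
    }
    u64 select0(u64 rank) const { // position of the (rank+1)-th zero
        u64 seen = 0;
        for (u64 wi = 0; wi < high.words.size(); ++wi) {
            u64 w = ~high.words[wi];
            u64 limit = std::min<u64>(64, high.nbits - wi * 64);
            int c = __builtin_popcountll(limit == 64 ? w : (w & ((1ULL << limit) - 1)));
            if (seen + (u64)c > rank) {
                u64 need = rank - seen;
                for (u64 b = 0; b < limit; ++b) {
                    if ((w >> b) & 1) {
                        if (need == 0) return wi * 64 + b;
                        --need;
                    }
                }
            }
            seen += (u64)c;
        }
        throw std::runtime_error("select0 out of range");
    }
    u64 ones_before_zero(u64 hx) const { // #ones strictly before the hx-th zero
        u64 p = select0(hx - 1);
        u64 ones = 0;
        for (u64 wi = 0; wi * 64 < p; ++wi) {
            u64 limit = std::min<u64>(64, p - wi * 64);
            u64 w = high.words[wi];
            ones += (u64)__builtin_popcountll(limit == 64 ? w : (w & ((1ULL << limit) - 1)));
        }
        return ones;
    }
};

} // namespace kmerdict

#endif
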
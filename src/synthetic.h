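#ifndef KMERDICT_SYNTHETIC_H
#define KMERDICT_SYNTHETIC_H

// Synthetic SPSS and read-set generation.  The SPSS generator emulates the
// output of a compaction pipeline (unitigs/eulertigs): strings of length
// >= k whose k-mers are pairwise distinct up to reverse complement.
// Distinctness is enforced during generation: each appended base is checked
// against the set of canonical k-mers emitted so far, and a string restarts
// from scratch in the (rare) event that no base can extend it.

#include <unordered_set>
#include "index.h"

namespace kmerdict {

inline std::vector<std::string> gen_spss(u64 total_bases, u64 n_strings, int k,
                                         u64 seed, double rc_fraction) {
    if (k < 1 || k > 63) throw std::runtime_error("k must be in [1, 63]");
    if (n_strings < 1) throw std::runtime_error("need at least one string");
    if (total_bases < n_strings * (u64)k)
        throw std::runtime_error("total_bases too small: need at least k bases per string");
    Rng rng(seed);
    std::vector<u64> lens(n_strings, total_bases / n_strings);
    for (u64 i = 0; i < total_bases % n_strings; ++i) lens[i] += 1;

    std::unordered_set<u128, U128Hash> used;
    u128 mask2k = (((u128)1) << (2 * k)) - 1;
    std::vector<std::string> out;
    out.reserve(n_strings);
    for (u64 si = 0; si < n_strings; ++si) {
        bool done = false;
        for (int attempt = 0; attempt < 200 && !done; ++attempt) {
            std::string s;
            s.reserve(lens[si]);
            std::vector<u128> added;
            u128 xf = 0, xr = 0;
            bool fail = false;
            for (u64 t = 1; t <= lens[si] && !fail; ++t) {
                int first = (int)rng.below(4);
                bool placed = false;
                for (int d = 0; d < 4; ++d) {
                    int b = (first + d) & 3;
                    u128 nf = ((xf << 2) | (u128)b) & mask2k;
                    u128 nr = (xr >> 2) | ((u128)(3 - b) << (2 * (k - 1)));
                    if (t >= (u64)k) {
                        u128 key = std::min(nf, nr);
                        if (used.count(key)) continue;
                        used.insert(key);
                        added.push_back(key);
                    }
                    xf = nf; xr = nr;
                    s.push_back(base_char(b));
                    placed = true;
                    break;
                }
                if (!placed) fail = true;
            }
            if (fail) {
                for (u128 key : added) used.erase(key);
                continue;
            }
            if (rng.unif() < rc_fraction) s = rc_string(s);
            out.push_back(s);
            done = true;
        }
        if (!done)
            throw std::runtime_error("SPSS generation failed: k-mer space too saturated "
                                     "for the requested size (increase k or reduce bases)");
    }
    return out;
}

struct ReadOrigin {
    u64 string_id = 0; // 0 for foreign reads
    u64 start = 0;
    bool revcomp = false;
    u64 n_subs = 0;
};

inline void gen_reads(const std::vector<std::string>& strings, u64 n_reads, u64 read_len,
                      double sub_rate, double foreign_frac, double rc_frac, u64 seed,
                      std::vector<std::string>& reads, std::vector<ReadOrigin>& origin) {
    Rng rng(seed);
    std::vector<u64> eligible, cum;
    u64 tot = 0;
    for (u64 i = 0; i < strings.size(); ++i) {
        if (strings[i].size() >= read_len) {
            eligible.push_back(i);
            tot += strings[i].size() - read_len + 1;
            cum.push_back(tot);
        }
    }
    if (foreign_frac < 1.0 && eligible.empty())
        throw std::runtime_error("no SPSS string is as long as the requested read length");
    reads.clear(); origin.clear();
    for (u64 r = 0; r < n_reads; ++r) {
        ReadOrigin o;
        std::string s;
        if (rng.unif() < foreign_frac) {
            s.resize(read_len);
            for (u64 t = 0; t < read_len; ++t) s[t] = base_char((int)rng.below(4));
        } else {
            u64 u = rng.below(tot);
            u64 e = 0;
            while (cum[e] <= u) ++e;
            u64 prev = (e == 0) ? 0 : cum[e - 1];
            o.string_id = eligible[e] + 1;
            o.start = u - prev + 1;
            s = strings[eligible[e]].substr(o.start - 1, read_len);
            // a "substitution" draws a uniform base, so one in four leaves
            // the base unchanged (effective change rate = 3/4 of sub_rate)
            for (u64 t = 0; t < read_len; ++t) {
                if (rng.unif() < sub_rate) {
                    int b = base_code(s[t]);
                    int nb = (int)rng.below(4);
                    s[t] = base_char(nb);
                    if (nb != b) ++o.n_subs;
                }
            }
            if (rng.unif() < rc_frac) { s = rc_string(s); o.revcomp = true; }
        }
        reads.push_back(s);
        origin.push_back(o);
    }
}

// Reference membership oracle: a plain hash set over the k-mers of strings.
// Independent of the index data path; used for validation.
inline std::vector<bool> kmer_membership(const std::vector<std::string>& strings, int k,
                                         const std::vector<std::string>& queries,
                                         bool canonical) {
    std::unordered_set<u128, U128Hash> set;
    for (const std::string& s : strings) {
        if ((int)s.size() < k) continue;
        for (size_t w = 0; w + k <= s.size(); ++w) {
            u128 xf = encode_be(s.substr(w, k));
            set.insert(canonical ? std::min(xf, rc_be(xf, k)) : xf);
        }
    }
    std::vector<bool> out(queries.size(), false);
    for (size_t i = 0; i < queries.size(); ++i) {
        const std::string& q = queries[i];
        if ((int)q.size() != k) continue;
        bool bad = false;
        for (char c : q) if (base_code(c) < 0) { bad = true; break; }
        if (bad) continue;
        u128 xf = encode_be(q);
        out[i] = set.count(canonical ? std::min(xf, rc_be(xf, k)) : xf) > 0;
    }
    return out;
}

} // namespace kmerdict

#endif
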
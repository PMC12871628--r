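#ifndef KMERDICT_MPHF_H
#define KMERDICT_MPHF_H

// Minimal perfect hash function over integer key sets (up to 128-bit keys)
// using bucket placement: keys hash into ~M/4 buckets; buckets are processed
// in decreasing size order and each receives a "pilot" value searched until
// all its keys land on free slots of a size-M table.  Evaluation is two
// hashes and one pilot fetch.  Foreign keys evaluate to arbitrary in-range
// values.

#include "common.h"

namespace kmerdict {

struct Mphf {
    u64 M = 0, nbuck = 0, seed = 0;
    IntVec pilots;

    static u64 slot(u64 h0, u64 pilot, u64 seed, u64 M) {
        return splitmix64(h0 ^ splitmix64(seed ^ (pilot * 0x9E3779B97F4A7C15ULL + 1))) % M;
    }

    void build(const std::vector<u128>& keys, u64 seed0) {
        M = keys.size();
        if (M == 0) throw std::runtime_error("MPHF requires at least one key");
        {
            std::vector<u128> srt(keys);
            std::sort(srt.begin(), srt.end());
            for (u64 i = 1; i < M; ++i)
                if (srt[i] == srt[i - 1])
                    throw std::runtime_error("MPHF keys must be distinct (duplicate key found)");
        }
        nbuck = std::max<u64>(1, (M + 3) / 4);
        const u64 PILOT_MAX = 1ULL << 24;
        for (int attempt = 0; attempt < 64; ++attempt) {
            seed = splitmix64(seed0 + (u64)attempt * 0x0123456789ABCDEFULL);
            std::vector<u64> h0(M);
            bool dup = false;
            for (u64 i = 0; i < M; ++i) h0[i] = hash_u128(keys[i], seed);
            {
                std::vector<u64> srt(h0);
                std::sort(srt.begin(), srt.end());
                for (u64 i = 1; i < M; ++i)
                    if (srt[i] == srt[i - 1]) { dup = true; break; }
            }
            if (dup) continue;
            std::vector<std::vector<u64>> bucket(nbuck);
            for (u64 i = 0; i < M; ++i) bucket[h0[i] % nbuck].push_back(h0[i]);
            std::vector<u64> order(nbuck);
            for (u64 b = 0; b < nbuck; ++b) order[b] = b;
            std::stable_sort(order.begin(), order.end(), [&](u64 a, u64 b) {
                return bucket[a].size() > bucket[b].size();
            });
            std::vector<u64> pil(nbuck, 0);
            BitVec taken; taken.resize(M);
            bool ok = true;
            std::vector<u64> pos;
            for (u64 oi = 0; oi < nbuck && ok; ++oi) {
                u64 b = order[oi];
                const std::vector<u64>& ks = bucket[b];
                if (ks.empty()) continue;
                bool placed = false;
                for (u64 p = 0; p < PILOT_MAX; ++p) {
                    pos.clear();
                    bool clash = false;
                    for (u64 h : ks) {
                        u64 s = slot(h, p, seed, M);
                        if (taken.get(s)) { clash = true; break; }
                        for (u64 q : pos) if (q == s) { clash = true; break; }
                        if (clash) break;
                        pos.push_back(s);
                    }
                    if (!clash) {
                        for (u64 s : pos) taken.set(s);
                        pil[b] = p;
                        placed = true;
                        break;
                    }
                }
                if (!placed) ok = false;
            }
            if (!ok) continue;
            u64 maxp = 0;
            for (u64 p : pil) maxp = std::max(maxp, p);
            pilots.resize(nbuck, bits_needed(maxp));
            for (u64 b = 0; b < nbuck; ++b) pilots.set(b, pil[b]);
            return;
        }
        throw std::runtime_error(
            "MPHF construction failed after 64 seed attempts; retry with a different seed");
    }

    u64 eval(u128 key) const { // in [1..M]
        u64 h0 = hash_u128(key, seed);
        u64 p = pilots.get(h0 % nbuck);
        return slot(h0, p, seed, M) + 1;
    }

    u64 size_bits() const { return pilots.bits() + 4 * 64; }
    double bits_per_key() const { return (double)size_bits() / (double)M; }

    void save(Writer& w) const {
        w.put_u64(M); w.put_u64(nbuck); w.put_u64(seed); w.put_u64((u64)pilots.w);
        w.put_words(pilots.words);
    }
    void load(Reader& r) {
        M = r.get_u64(); nbuck = r.get_u64(); seed = r.get_u64();
        int w = (int)r.get_u64();
        std::vector<u64> ws; r.get_words(ws);
        pilots.resize(nbuck, w);
        std::copy(ws.begin(), ws.end(), pilots.words.begin());
    }
};

} // namespace kmerdict

#endif
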
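#ifndef KMERDICT_LAYOUT_H
#define KMERDICT_LAYOUT_H

// Three-type storage of locate sets, indexed by the minimizer MPHF f:
//   tag array T (one word per minimizer, width ceil(log2 N)+1, widened only
//   when a tiny input cannot address its own stores),
//   light store (L grouped by set size z with group directory G),
//   heavy store (H, concatenated locate sets) resolved through a skew index
//   of up to 8 partitions (f_i, V_i).
//
// Tag bit layout, least significant bits first:
//   singleton: [0 | position-1]
//   light:     [1 0 | z-2 (l bits) | group index]
//   heavy:     [1 1 | partition id - l (3 bits) | offset o]
// Positions are stored as value-1 so that they fit ceil(log2 N) bits.

#include "mphf.h"
#include "minimizer.h"

namespace kmerdict {

inline int skew_partition_of(u64 z, int l, int r) {
    int i = l;
    while (i < r && z > (1ULL << (i + 1))) ++i;
    return i;
}

struct SkewPartition {
    int i = 0;       // partition id in [l..r]
    Mphf f;          // over the k-mer keys of K_i
    IntVec V;        // locate-set indices (0-based), width i+1 (or log2 max at i=r)
};

struct ProbeCount {
    u64 L = 0, H = 0, V = 0, G = 0;
};

struct LocateHit {
    int type = 0;            // 0 singleton, 1 light, 2 heavy
    bool anchor_ok = false;  // minimizer verified present at its first position
    std::vector<u64> candidates; // absolute positions j
};

// Build-time description of one minimizer's locate set.
struct LocEntry {
    u64 value = 0;              // minimizer key (m-mer BE code; canonical in canonical mode)
    std::vector<u64> pos;       // sorted distinct absolute positions in S
};

// k-mers of heavy minimizers: key (possibly canonical) plus the 0-based index
// of its occurrence inside loc(value).
struct HeavyKmer {
    u128 key;
    u64 value;
    u64 loc_index;
};

struct Layout {
    int l = 6, r = 13;
    u64 N = 0, M = 0;
    int pw = 1;            // position width = ceil(log2 N)
    int tagw = 2;          // tag width (>= pw + 1; widened on tiny inputs)
    bool widened = false;
    IntVec T;
    std::vector<u64> G;    // G[z] = start (entry units) of size-z group in L, z in [2..2^l]
    IntVec L, H;
    std::vector<SkewPartition> parts;
    u64 n_singleton = 0, maxloc = 0;

    // occ must be ordered deterministically (by minimizer key); f must be a
    // MPHF over exactly the values in occ.
    void build(const std::vector<LocEntry>& occ, const std::vector<HeavyKmer>& heavy,
               const Mphf& f, int l_, int r_, u64 N_, u64 seed) {
        l = l_; r = r_; N = N_; M = occ.size();
        if (l < 1) throw std::runtime_error("l must be >= 1");
        if (r - l + 1 > 8) throw std::runtime_error("skew partition id must fit 3 bits (r-l+1 <= 8)");
        pw = bits_needed(N > 0 ? N - 1 : 0);
        n_singleton = 0; maxloc = 0;

        std::vector<u64> tvals(M), zvals(M);
        std::vector<u64> order(M);
        for (u64 a = 0; a < M; ++a) {
            tvals[a] = f.eval((u128)occ[a].value);
            zvals[a] = occ[a].pos.size();
            if (zvals[a] > maxloc) maxloc = zvals[a];
            if (zvals[a] == 1) ++n_singleton;
            order[a] = a;
        }
        // deterministic placement order: by tag slot
        std::sort(order.begin(), order.end(), [&](u64 a, u64 b) { return tvals[a] < tvals[b]; });

        u64 zmax_light = 1ULL << l;
        // ---- light store ----
        std::vector<u64> light_entries;
        std::vector<u64> gindex(M, 0);
        G.assign(zmax_light + 2, 0);
        u64 gi_max = 0;
        for (u64 z = 2; z <= zmax_light; ++z) {
            G[z] = light_entries.size();
            u64 gi = 0;
            for (u64 a : order) {
                if (zvals[a] != z) continue;
                gindex[a] = gi++;
                for (u64 p : occ[a].pos) light_entries.push_back(p - 1);
            }
            if (gi > 0) gi_max = std::max(gi_max, gi - 1);
        }
        G[zmax_light + 1] = light_entries.size();
        L.resize(light_entries.size(), pw);
        for (u64 i = 0; i < light_entries.size(); ++i) L.set(i, light_entries[i]);

        // ---- heavy store ----
        std::vector<u64> heavy_entries;
        std::vector<u64> hoffset(M, 0);
        for (u64 a : order) {
            if (zvals[a] <= zmax_light) continue;
            hoffset[a] = heavy_entries.size();
            for (u64 p : occ[a].pos) heavy_entries.push_back(p - 1);
        }
        H.resize(heavy_entries.size(), pw);
        for (u64 i = 0; i < heavy_entries.size(); ++i) H.set(i, heavy_entries[i]);
        u64 o_max = heavy_entries.empty() ? 0 : heavy_entries.size() - 1;

        // ---- tag width (widen on tiny inputs that cannot address stores) ----
        int need = pw + 1;
        need = std::max(need, 2 + l + bits_needed(gi_max));
        if (!heavy_entries.empty()) need = std::max(need, 5 + bits_needed(o_max));
        tagw = need;
        widened = tagw > pw + 1;
        if (tagw > 64) throw std::runtime_error("tag word exceeds 64 bits");

        // ---- tags ----
        T.resize(M, tagw);
        for (u64 a = 0; a < M; ++a) {
            u64 tag;
            if (zvals[a] == 1) {
                tag = (occ[a].pos[0] - 1) << 1; // [0 | position-1]
            } else if (zvals[a] <= zmax_light) {
                tag = 1ULL | (0ULL << 1) | ((zvals[a] - 2) << 2) | (gindex[a] << (2 + l));
            } else {
                u64 part = (u64)(skew_partition_of(zvals[a], l, r) - l);
                tag = 1ULL | (1ULL << 1) | (part << 2) | (hoffset[a] << 5);
            }
            T.set(tvals[a] - 1, tag);
        }

        // ---- skew index ----
        parts.clear();
        if (!heavy.empty()) {
            std::vector<u64> locsize; // per minimizer value, for partitioning
            std::vector<std::vector<const HeavyKmer*>> by_part(r - l + 1);
            // map value -> loc size (values are few; reuse occ order lookup)
            std::vector<std::pair<u64, u64>> vz(M);
            for (u64 a = 0; a < M; ++a) vz[a] = {occ[a].value, zvals[a]};
            std::sort(vz.begin(), vz.end());
            for (const HeavyKmer& hk : heavy) {
                auto it = std::lower_bound(vz.begin(), vz.end(),
                                           std::make_pair(hk.value, (u64)0));
                if (it == vz.end() || it->first != hk.value)
                    throw std::runtime_error("heavy k-mer refers to unknown minimizer");
                int i = skew_partition_of(it->second, l, r);
                by_part[i - l].push_back(&hk);
            }
            for (int i = l; i <= r; ++i) {
                const std::vector<const HeavyKmer*>& ks = by_part[i - l];
                if (ks.empty()) continue;
                SkewPartition sp;
                sp.i = i;
                std::vector<u128> keys(ks.size());
                for (size_t t = 0; t < ks.size(); ++t) keys[t] = ks[t]->key;
                sp.f.build(keys, splitmix64(seed + (u64)i));
                int vw = (i < r) ? (i + 1) : bits_needed(maxloc > 0 ? maxloc - 1 : 0);
                sp.V.resize(ks.size(), vw);
                for (size_t t = 0; t < ks.size(); ++t)
                    sp.V.set(sp.f.eval(ks[t]->key) - 1, ks[t]->loc_index);
                parts.push_back(std::move(sp));
            }
        }
    }

    int decode_type(u64 tag) const {
        if ((tag & 1) == 0) return 0;
        return ((tag >> 1) & 1) ? 2 : 1;
    }

    // Resolve the locate set reachable through tag slot t for a k-mer with
    // key kkey (only used on the heavy path).  `have_key` is false when the
    // caller wants the whole set (e.g., in tests).
    LocateHit locate(u64 t, u64 kkey_mmer, u128 kkey_kmer, bool have_key,
                     const PackedSeq& S, int m, bool canonical, ProbeCount* pc) const {
        LocateHit out;
        u64 tag = T.get(t - 1);
        out.type = decode_type(tag);
        if (out.type == 0) {
            u64 j = (tag >> 1) + 1;
            out.anchor_ok = mmer_matches(S, j, m, kkey_mmer, canonical);
            if (out.anchor_ok) out.candidates.push_back(j);
            return out;
        }
        if (out.type == 1) {
            u64 z = ((tag >> 2) & ((1ULL << l) - 1)) + 2;
            u64 gi = tag >> (2 + l);
            if (pc) pc->G += 1;
            u64 start = G[z] + gi * z;
            if (start + z > L.n) { out.anchor_ok = false; return out; }
            u64 j0 = L.get(start) + 1;
            if (pc) pc->L += 1;
            out.anchor_ok = mmer_matches(S, j0, m, kkey_mmer, canonical);
            if (!out.anchor_ok) return out;
            out.candidates.push_back(j0);
            for (u64 u = 1; u < z; ++u) {
                if (pc) pc->L += 1;
                out.candidates.push_back(L.get(start + u) + 1);
            }
            return out;
        }
        // heavy
        int i = l + (int)((tag >> 2) & 7);
        u64 o = tag >> 5;
        const SkewPartition* sp = nullptr;
        for (const SkewPartition& p : parts) if (p.i == i) { sp = &p; break; }
        if (sp == nullptr || !have_key || o >= H.n) {
            // no partition (corrupt/foreign) -- fall back to anchor check only
            if (o < H.n) {
                if (pc) pc->H += 1;
                out.anchor_ok = mmer_matches(S, H.get(o) + 1, m, kkey_mmer, canonical);
            }
            return out;
        }
        u64 v = sp->V.get(sp->f.eval(kkey_kmer) - 1);
        if (pc) pc->V += 1;
        u64 idx = o + v;
        if (idx < H.n) {
            if (pc) pc->H += 1;
            u64 j = H.get(idx) + 1;
            if (mmer_matches(S, j, m, kkey_mmer, canonical)) {
                out.anchor_ok = true;
                out.candidates.push_back(j);
                return out;
            }
        }
        // candidate slot failed: one extra probe at the set's first entry
        // decides whether the minimizer itself is present (soundness of the
        // `found` flag; only reached for k-mers not in the index).
        if (pc) pc->H += 1;
        out.anchor_ok = mmer_matches(S, H.get(o) + 1, m, kkey_mmer, canonical);
        return out;
    }

    static bool mmer_matches(const PackedSeq& S, u64 j, int m, u64 value, bool canonical) {
        if (S.N == 0) return true; // standalone layout: no sequence to verify against
        if (j < 1 || j + (u64)m - 1 > S.N) return false;
        u64 mm = S.extract_be64(j, m);
        if (mm == value) return true;
        if (canonical) return rc_be64(mm, m) == value;
        return false;
    }

    u64 bits_T() const { return T.bits(); }
    u64 bits_L() const { return L.bits(); }
    u64 bits_H() const { return H.bits(); }
    u64 bits_G() const { return 64 * (u64)G.size(); } // stored uncompressed
    u64 bits_skew() const {
        u64 b = 0;
        for (const SkewPartition& p : parts) b += p.f.size_bits() + p.V.bits();
        return b;
    }

    void save(Writer& w) const {
        w.put_u64((u64)l); w.put_u64((u64)r); w.put_u64(N); w.put_u64(M);
        w.put_u64((u64)pw); w.put_u64((u64)tagw); w.put_u64(widened ? 1 : 0);
        w.put_u64(n_singleton); w.put_u64(maxloc);
        w.put_u64(T.n); w.put_words(T.words);
        w.put_words(G);
        w.put_u64(L.n); w.put_words(L.words);
        w.put_u64(H.n); w.put_words(H.words);
        w.put_u64(parts.size());
        for (const SkewPartition& p : parts) {
            w.put_u64((u64)p.i);
            p.f.save(w);
            w.put_u64((u64)p.V.w); w.put_u64(p.V.n); w.put_words(p.V.words);
        }
    }
    void load(Reader& rd) {
        l = (int)rd.get_u64(); r = (int)rd.get_u64(); N = rd.get_u64(); M = rd.get_u64();
        pw = (int)rd.get_u64(); tagw = (int)rd.get_u64(); widened = rd.get_u64() != 0;
        n_singleton = rd.get_u64(); maxloc = rd.get_u64();
        u64 tn = rd.get_u64(); std::vector<u64> ws; rd.get_words(ws);
        T.resize(tn, tagw); std::copy(ws.begin(), ws.end(), T.words.begin());
        rd.get_words(G);
        u64 ln = rd.get_u64(); rd.get_words(ws);
        L.resize(ln, pw); std::copy(ws.begin(), ws.end(), L.words.begin());
        u64 hn = rd.get_u64(); rd.get_words(ws);
        H.resize(hn, pw); std::copy(ws.begin(), ws.end(), H.words.begin());
        u64 np = rd.get_u64();
        parts.assign(np, SkewPartition());
        for (u64 t = 0; t < np; ++t) {
            parts[t].i = (int)rd.get_u64();
            parts[t].f.load(rd);
            int vw = (int)rd.get_u64();
            u64 vn = rd.get_u64();
            rd.get_words(ws);
            parts[t].V.resize(vn, vw);
            std::copy(ws.begin(), ws.end(), parts[t].V.words.begin());
        }
    }
};

} // namespace kmerdict

#endif
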
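#ifndef KMERDICT_INDEX_H
#define KMERDICT_INDEX_H

// Index assembly and queries: LOOKUP (regular and canonical, with refined
// displacements), ACCESS, and space accounting.

#include <unordered_map>
#include <unordered_set>
#include "ef.h"
#include "layout.h"

namespace kmerdict {

struct U128Hash {
    size_t operator()(const u128& x) const {
        return (size_t)hash_u128(x, 0x5bd1e995U);
    }
};

struct Params {
    int k = 31, m = 15, l = 6, r = 13;
    bool canonical = true;
    bool lex = false;
    u64 seed = 1;
};

struct LookupRes {
    bool match = false;
    bool found = false;        // minimizer (any attempted strand) present in S
    bool found_f = false, found_r = false;
    u64 h = 0, i = 0, q = 0;
    int orient = 0;
    u64 mmer_f = 0, mmer_r = 0; // per-strand minimizer values (regular mode)
    u64 cvalue = 0;             // canonical minimizer value (canonical mode)
};

struct Index {
    Params par;
    PackedSeq S;
    std::vector<u64> P;  // start positions p_1..p_{|S|} plus sentinel N+1
    EliasFano efP;
    Mphf f;              // over minimizer values
    Layout lay;
    u64 n = 0, N = 0, M = 0, Z = 0, n_super = 0, alpha = 0;
    u64 n_strings = 0;

    MinOrder order() const {
        MinOrder O;
        O.lex = par.lex;
        O.seed = splitmix64(par.seed ^ 0xC0FFEE123456789ULL);
        O.m = par.m;
        return O;
    }

    // ---------------- construction ----------------

    void build(const std::vector<std::string>& strings, const Params& p) {
        par = p;
        const int k = par.k, m = par.m;
        if (k < 1 || k > 63) throw std::runtime_error("k must be in [1, 63]");
        if (m < 1 || m >= k) throw std::runtime_error("m must satisfy 1 <= m < k");
        if (m > 31) throw std::runtime_error("m must be <= 31");
        if (strings.empty()) throw std::runtime_error("SPSS must contain at least one string");
        MinOrder O = order();

        // pack
        u64 total = 0;
        for (size_t i = 0; i < strings.size(); ++i) {
            check_dna(strings[i], "SPSS string");
            if ((int)strings[i].size() < k)
                throw std::runtime_error("SPSS string " + std::to_string(i + 1) +
                                         " is shorter than k");
            total += strings[i].size();
        }
        S.reserve_bases(total);
        P.clear();
        for (const std::string& s : strings) {
            P.push_back(S.N + 1);
            for (char c : s) S.push(base_code(c));
        }
        N = S.N;
        P.push_back(N + 1);
        n_strings = strings.size();
        efP.build(P, N + 1);

        // enumerate windows; duplicate check; super-k-mer runs
        std::unordered_map<u128, std::pair<u64, u64>, U128Hash> seen;
        std::vector<SuperKmer> runs, all_runs;
        n = 0;
        for (u64 si = 0; si < n_strings; ++si) {
            u64 base = P[si];
            u64 len = P[si + 1] - P[si];
            u64 nw = len - k + 1;
            n += nw;
            auto get_window = [&](u64 w) { return S.extract_be(base + w - 1, k); };
            for (u64 w = 1; w <= nw; ++w) {
                u128 xf = get_window(w);
                u128 key = par.canonical ? std::min(xf, rc_be(xf, k)) : xf;
                auto it = seen.find(key);
                if (it != seen.end())
                    throw std::runtime_error(
                        "duplicate k-mer " + decode_be(xf, k) + " at string " +
                        std::to_string(si + 1) + " position " + std::to_string(w) +
                        " (first seen at string " + std::to_string(it->second.first) +
                        " position " + std::to_string(it->second.second) + ")");
                seen.emplace(key, std::make_pair(si + 1, w));
            }
            parse_runs(nw, k, m, O, par.canonical, get_window, runs);
            for (SuperKmer& r : runs) { // to absolute coordinates
                r.j += base - 1;
                r.win_start += base - 1;
                all_runs.push_back(r);
            }
        }
        n_super = all_runs.size();

        // locate sets
        std::unordered_map<u64, std::vector<u64>> occmap;
        for (const SuperKmer& r : all_runs) occmap[r.value].push_back(r.j);
        std::vector<LocEntry> occ;
        occ.reserve(occmap.size());
        for (auto& kv : occmap) {
            std::sort(kv.second.begin(), kv.second.end());
            kv.second.erase(std::unique(kv.second.begin(), kv.second.end()), kv.second.end());
            occ.push_back({kv.first, kv.second});
        }
        std::sort(occ.begin(), occ.end(),
                  [](const LocEntry& a, const LocEntry& b) { return a.value < b.value; });
        M = occ.size();
        Z = 0;
        for (const LocEntry& e : occ) Z += e.pos.size();

        // minimizer MPHF
        std::vector<u128> mkeys(M);
        for (u64 a = 0; a < M; ++a) mkeys[a] = (u128)occ[a].value;
        f.build(mkeys, splitmix64(par.seed ^ 0xF00DF00DULL));

        // heavy k-mers with per-k-mer locate index
        u64 zmax_light = 1ULL << par.l;
        std::unordered_map<u64, u64> locsize;
        std::unordered_map<u64, const std::vector<u64>*> locref;
        for (const LocEntry& e : occ) {
            locsize[e.value] = e.pos.size();
            locref[e.value] = &e.pos;
        }
        std::vector<HeavyKmer> heavy;
        alpha = 0;
        for (const SuperKmer& r : all_runs) {
            if (locsize[r.value] <= zmax_light) continue;
            const std::vector<u64>& loc = *locref[r.value];
            u64 li = (u64)(std::lower_bound(loc.begin(), loc.end(), r.j) - loc.begin());
            for (u64 t = 0; t < r.n_kmers; ++t) {
                u128 xf = S.extract_be(r.win_start + t, k);
                u128 key = par.canonical ? std::min(xf, rc_be(xf, k)) : xf;
                heavy.push_back({key, r.value, li});
            }
        }
        alpha = heavy.size();

        lay.build(occ, heavy, f, par.l, par.r, N, splitmix64(par.seed ^ 0xABCDEF987ULL));
    }

    double beta() const { return M == 0 ? 0.0 : 1.0 - (double)lay.n_singleton / (double)M; }

    // ---------------- queries ----------------

    // string id i such that p_i <= q <= p_{i+1} - k, or 0 when the window
    // would cross a string boundary.
    u64 string_of(u64 q) const {
        if (q < 1 || q + (u64)par.k - 1 > N) return 0;
        std::pair<u64, u64> s = efP.successor(q);
        u64 i = (s.second == q) ? s.first : s.first - 1;
        if (i < 1 || i > n_strings) return 0;
        u64 pnext = efP.access(i + 1);
        if (q + (u64)par.k > pnext) return 0;
        return i;
    }

    u64 handle_of(u64 q, u64 i) const { return q - (i - 1) * (u64)(par.k - 1); }

    // defined below (free function shared with the streaming seed path)
    LookupRes lookup_code(u128 xf, u128 xr) const;

    LookupRes lookup(const std::string& x) const {
        if ((int)x.size() != par.k)
            throw std::runtime_error("query k-mer has length " + std::to_string(x.size()) +
                                     ", expected k = " + std::to_string(par.k));
        for (char c : x) {
            if (base_code(c) < 0) { LookupRes r; return r; } // non-ACGT: miss
        }
        u128 xf = encode_be(x);
        return lookup_code(xf, rc_be(xf, par.k));
    }

    std::string access(u64 h) const {
        if (h < 1 || h > n) return "";
        // largest i with first_handle(i) <= h, first_handle(i) = p_i - (i-1)(k-1)
        u64 lo = 1, hi = n_strings, i = 1;
        while (lo <= hi) {
            u64 mid = (lo + hi) / 2;
            u64 fh = P[mid - 1] - (mid - 1) * (u64)(par.k - 1);
            if (fh <= h) { i = mid; lo = mid + 1; } else { hi = mid - 1; }
        }
        u64 q = h + (i - 1) * (u64)(par.k - 1);
        return S.extract_str(q, par.k);
    }

    // ---------------- serialization ----------------

    void save(Writer& w) const {
        w.put_u64(0x3158444B52454D4BULL); // magic "KMERKDX1"
        w.put_u64(1);                     // version
        std::vector<u64> hdr = {
            (u64)par.k, (u64)par.m, (u64)par.l, (u64)par.r,
            par.canonical ? 1ULL : 0ULL, par.lex ? 1ULL : 0ULL, par.seed,
            n, N, M, Z, n_super, alpha, n_strings};
        u64 ck = 0xDEADC0DEULL;
        for (u64 v : hdr) { w.put_u64(v); ck = splitmix64(ck ^ v); }
        w.put_u64(ck);
        w.put_words(S.words); w.put_u64(S.N);
        efP.save(w);
        f.save(w);
        lay.save(w);
    }

    void load(Reader& r) {
        if (r.get_u64() != 0x3158444B52454D4BULL)
            throw std::runtime_error("not a kmerdict index file (bad magic bytes)");
        if (r.get_u64() != 1) throw std::runtime_error("unsupported index version");
        std::vector<u64> hdr(14);
        u64 ck = 0xDEADC0DEULL;
        for (u64& v : hdr) { v = r.get_u64(); ck = splitmix64(ck ^ v); }
        if (r.get_u64() != ck) throw std::runtime_error("index header checksum mismatch");
        par.k = (int)hdr[0]; par.m = (int)hdr[1]; par.l = (int)hdr[2]; par.r = (int)hdr[3];
        par.canonical = hdr[4] != 0; par.lex = hdr[5] != 0; par.seed = hdr[6];
        n = hdr[7]; N = hdr[8]; M = hdr[9]; Z = hdr[10]; n_super = hdr[11];
        alpha = hdr[12]; n_strings = hdr[13];
        r.get_words(S.words);
        S.N = r.get_u64();
        efP.load(r);
        f.load(r);
        lay.load(r);
        P.resize(n_strings + 1);
        for (u64 i = 1; i <= n_strings + 1; ++i) P[i - 1] = efP.access(i);
    }
};

// The complete LOOKUP pipeline from precomputed per-strand minimizer hits.
// Both random lookup and the streaming Seed go through this single function,
// so their answers agree whenever their minimizer hits do.
inline LookupRes lookup_with_hits(const Index& ix, u128 xf, u128 xr,
                                  const MinimizerHit& hf, const MinimizerHit& hr) {
    const int k = ix.par.k, m = ix.par.m;
    MinOrder O = ix.order();
    LookupRes res;
    if (ix.par.canonical) {
        CanonicalHit h;
        h.fwd = hf; h.rev = hr;
        if (O.less(hf.mmer, hr.mmer)) h.cmp = -1;
        else if (O.less(hr.mmer, hf.mmer)) h.cmp = +1;
        else h.cmp = 0;
        if (h.cmp <= 0) { h.mmer = hf.mmer; h.pos = hf.pos; }
        else { h.mmer = hr.mmer; h.pos = rc_position(k, m, hr.pos); }
        res.cvalue = h.mmer; res.mmer_f = hf.mmer; res.mmer_r = hr.mmer;
        u128 kkey = std::min(xf, xr);
        u64 t = ix.f.eval((u128)h.mmer);
        LocateHit lh = ix.lay.locate(t, h.mmer, kkey, true, ix.S, m, true, nullptr);
        res.found = res.found_f = res.found_r = lh.anchor_ok;
        if (!lh.anchor_ok) return res;
        std::vector<Disp> ds;
        canonical_disps(h, k, m, ds);
        for (u64 j : lh.candidates) {
            for (const Disp& d : ds) {
                if ((u64)d.d > j) continue; // q would be < 1
                u64 q = j - (u64)d.d + 1;
                u64 i = ix.string_of(q);
                if (i == 0) continue;
                u128 want = (d.orient > 0) ? xf : xr;
                if (ix.S.extract_be(q, k) == want) {
                    res.match = true;
                    res.q = q; res.i = i; res.orient = d.orient;
                    res.h = ix.handle_of(q, i);
                    return res;
                }
            }
        }
        return res;
    }
    // regular modality: the forward pipeline runs to completion, then rc
    res.mmer_f = hf.mmer; res.mmer_r = hr.mmer;
    {
        u64 t = ix.f.eval((u128)hf.mmer);
        LocateHit lh = ix.lay.locate(t, hf.mmer, xf, true, ix.S, m, false, nullptr);
        res.found_f = lh.anchor_ok;
        if (lh.anchor_ok) {
            for (u64 j : lh.candidates) {
                if ((u64)hf.pos > j) continue;
                u64 q = j - (u64)hf.pos + 1;
                u64 i = ix.string_of(q);
                if (i == 0) continue;
                if (ix.S.extract_be(q, k) == xf) {
                    res.match = true; res.found = true;
                    res.q = q; res.i = i; res.orient = +1;
                    res.h = ix.handle_of(q, i);
                    return res;
                }
            }
        }
    }
    {
        u64 t = ix.f.eval((u128)hr.mmer);
        LocateHit lh = ix.lay.locate(t, hr.mmer, xr, true, ix.S, m, false, nullptr);
        res.found_r = lh.anchor_ok;
        if (lh.anchor_ok) {
            for (u64 j : lh.candidates) {
                if ((u64)hr.pos > j) continue;
                u64 q = j - (u64)hr.pos + 1;
                u64 i = ix.string_of(q);
                if (i == 0) continue;
                if (ix.S.extract_be(q, k) == xr) {
                    res.match = true; res.found = true;
                    res.q = q; res.i = i; res.orient = -1;
                    res.h = ix.handle_of(q, i);
                    return res;
                }
            }
        }
    }
    res.found = res.found_f || res.found_r;
    return res;
}

inline LookupRes Index::lookup_code(u128 xf, u128 xr) const {
    MinOrder O = order();
    return lookup_with_hits(*this, xf, xr,
                            mini_code(xf, par.k, par.m, O),
                            mini_code(xr, par.k, par.m, O));
}

} // namespace kmerdict

#endif
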
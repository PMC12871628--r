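// Rcpp interface for the kmerdict core.

#include <Rcpp.h>
#include "stream.h"
#include "synthetic.h"

using namespace Rcpp;
using namespace kmerdict;

// ---------------------------------------------------------------- helpers

static RawVector words_to_raw(const std::vector<u64>& ws) {
    RawVector r(ws.size() * 8);
    for (size_t i = 0; i < ws.size(); ++i)
        for (int b = 0; b < 8; ++b)
            r[i * 8 + b] = (Rbyte)((ws[i] >> (8 * b)) & 0xFF);
    return r;
}

static std::vector<u64> raw_to_words(const RawVector& r) {
    if (r.size() % 8 != 0) stop("corrupt word payload");
    std::vector<u64> ws(r.size() / 8, 0);
    for (size_t i = 0; i < ws.size(); ++i)
        for (int b = 0; b < 8; ++b)
            ws[i] |= (u64)(unsigned char)r[i * 8 + b] << (8 * b);
    return ws;
}

static u64 as_u64(double x, const char* what) {
    if (ISNA(x) || x < 0 || x != std::floor(x) || x > 9007199254740992.0)
        stop("%s must be a non-negative integer below 2^53", what);
    return (u64)x;
}

static std::vector<std::string> as_strings(const CharacterVector& v) {
    std::vector<std::string> out(v.size());
    for (R_xlen_t i = 0; i < v.size(); ++i) out[i] = as<std::string>(v[i]);
    return out;
}

// ---------------------------------------------------------------- kmer_codec

// [[Rcpp::export]]
CharacterVector cpp_encode_kmers(CharacterVector s) {
    CharacterVector out(s.size());
    for (R_xlen_t i = 0; i < s.size(); ++i) {
        std::string x = as<std::string>(s[i]);
        if (x.size() < 1 || x.size() > 63) stop("k-mer length must be in [1, 63]");
        check_dna(x, "k-mer");
        u128 be = encode_be(x);
        out[i] = u128_to_dec(le_from_be(be, (int)x.size()));
    }
    return out;
}

// [[Rcpp::export]]
CharacterVector cpp_decode_kmers(CharacterVector codes, int k) {
    if (k < 1 || k > 63) stop("k must be in [1, 63]");
    CharacterVector out(codes.size());
    u128 limit = (((u128)1) << (2 * k));
    for (R_xlen_t i = 0; i < codes.size(); ++i) {
        u128 le = dec_to_u128(as<std::string>(codes[i]));
        if (le >= limit) stop("code is >= 4^k");
        // LE -> string: base at position p in bit pair p-1
        std::string s((size_t)k, 'A');
        for (int p = 0; p < k; ++p) { s[(size_t)p] = base_char((int)(le & 3)); le >>= 2; }
        out[i] = s;
    }
    return out;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector s) {
    CharacterVector out(s.size());
    for (R_xlen_t i = 0; i < s.size(); ++i)
        out[i] = rc_string(as<std::string>(s[i]));
    return out;
}

// [[Rcpp::export]]
List cpp_pack_spss(CharacterVector strings, int k, bool canonical) {
    if (k < 1 || k > 63) stop("k must be in [1, 63]");
    std::vector<std::string> ss = as_strings(strings);
    u64 total = 0;
    for (size_t i = 0; i < ss.size(); ++i) {
        check_dna(ss[i], "SPSS string");
        if ((int)ss[i].size() < k)
            stop("SPSS string %d has length %d < k = %d", (int)(i + 1),
                 (int)ss[i].size(), k);
        total += ss[i].size();
    }
    // duplicate k-mer check naming both occurrences
    std::unordered_map<u128, std::pair<u64, u64>, U128Hash> seen;
    u64 nk = 0;
    for (size_t i = 0; i < ss.size(); ++i) {
        for (size_t w = 0; w + k <= ss[i].size(); ++w) {
            u128 xf = encode_be(ss[i].substr(w, k));
            u128 key = canonical ? std::min(xf, rc_be(xf, k)) : xf;
            auto it = seen.find(key);
            if (it != seen.end())
                stop("duplicate k-mer %s: string %d position %d and string %d position %d",
                     decode_be(xf, k).c_str(), (int)it->second.first,
                     (int)it->second.second, (int)(i + 1), (int)(w + 1));
            seen.emplace(key, std::make_pair((u64)(i + 1), (u64)(w + 1)));
            ++nk;
        }
    }
    PackedSeq S;
    S.reserve_bases(total);
    NumericVector P(ss.size() + 1);
    for (size_t i = 0; i < ss.size(); ++i) {
        P[i] = (double)(S.N + 1);
        for (char c : ss[i]) S.push(base_code(c));
    }
    P[ss.size()] = (double)(S.N + 1);
    return List::create(_["packed"] = words_to_raw(S.words), _["N"] = (double)S.N,
                        _["P"] = P, _["k"] = k, _["n_strings"] = (int)ss.size(),
                        _["n_kmers"] = (double)nk, _["canonical"] = canonical);
}

// [[Rcpp::export]]
std::string cpp_spss_extract(RawVector packed, double N, double q, double w) {
    PackedSeq S;
    S.words = raw_to_words(packed);
    S.N = as_u64(N, "N");
    u64 qq = as_u64(q, "q"), ww = as_u64(w, "w");
    if (qq < 1 || ww < 1 || qq + ww - 1 > S.N)
        stop("extract window [%d, %d) is out of range 1..%d", (int)qq, (int)(qq + ww),
             (int)S.N);
    return S.extract_str(qq, (int)ww);
}

// ---------------------------------------------------------------- minimizer_engine

static MinOrder make_order(int m, bool lex, double seed) {
    MinOrder O;
    O.lex = lex;
    O.seed = splitmix64(as_u64(seed, "seed") ^ 0xC0FFEE123456789ULL);
    O.m = m;
    return O;
}

// [[Rcpp::export]]
List cpp_minimizer(std::string x, int m, bool lex, double seed, bool canonical) {
    int k = (int)x.size();
    if (m < 1 || m > 31 || m >= k) stop("need 1 <= m < k and m <= 31");
    check_dna(x, "k-mer");
    MinOrder O = make_order(m, lex, seed);
    u128 xf = encode_be(x);
    if (!canonical) {
        MinimizerHit h = mini_code(xf, k, m, O);
        return List::create(_["mmer"] = decode_be((u128)h.mmer, m), _["pos"] = h.pos);
    }
    CanonicalHit h = cmini_code(xf, rc_be(xf, k), k, m, O);
    return List::create(_["mmer"] = decode_be((u128)h.mmer, m), _["pos"] = h.pos);
}

// [[Rcpp::export]]
DataFrame cpp_parse_super_kmers(std::string s, int k, int m, bool lex, double seed,
                                bool canonical) {
    if ((int)s.size() < k) stop("string shorter than k");
    if (m < 1 || m > 31 || m >= k) stop("need 1 <= m < k and m <= 31");
    check_dna(s, "string");
    MinOrder O = make_order(m, lex, seed);
    PackedSeq S;
    S.reserve_bases(s.size());
    for (char c : s) S.push(base_code(c));
    u64 nw = s.size() - k + 1;
    std::vector<SuperKmer> runs;
    parse_runs(nw, k, m, O, canonical, [&](u64 w) { return S.extract_be(w, k); }, runs);
    R_xlen_t n = (R_xlen_t)runs.size();
    NumericVector start(n), end(n), nk(n), mpos(n);
    CharacterVector mmer(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        start[i] = (double)runs[i].win_start;
        end[i] = (double)(runs[i].win_start + runs[i].n_kmers - 1 + (u64)k - 1);
        nk[i] = (double)runs[i].n_kmers;
        mpos[i] = (double)runs[i].j;
        mmer[i] = decode_be((u128)runs[i].value, m);
    }
    return DataFrame::create(_["start"] = start, _["end"] = end, _["n_kmers"] = nk,
                             _["minimizer"] = mmer, _["min_pos"] = mpos,
                             _["stringsAsFactors"] = false);
}

// Rolling per-window minimizers of both strands (amortized O(1) maintenance).
// [[Rcpp::export]]
DataFrame cpp_streaming_minimizers(std::string s, int k, int m, bool lex, double seed) {
    if ((int)s.size() < k) stop("sequence shorter than k");
    if (m < 1 || m > 31 || m >= k) stop("need 1 <= m < k and m <= 31");
    check_dna(s, "sequence");
    MinOrder O = make_order(m, lex, seed);
    Index dummy; // only to carry parameters for ReadRoller
    dummy.par.k = k; dummy.par.m = m; dummy.par.lex = lex;
    dummy.par.seed = as_u64(seed, "seed");
    ReadRoller rr(&dummy);
    rr.O = O;
    long len = (long)s.size(), nw = len - k + 1;
    rr.fcodes.assign((size_t)(len + 2), 0);
    rr.rcodes.assign((size_t)(len + 2), 0);
    for (long e = 1; e < k; ++e) rr.feed(s[(size_t)(e - 1)], e);
    NumericVector start(nw), fpos(nw), rpos(nw);
    CharacterVector fmm(nw), rmm(nw);
    for (long ws = 1; ws <= nw; ++ws) {
        rr.feed(s[(size_t)(ws + k - 2)], ws + k - 1);
        rr.roll(ws, ws == 1);
        MinimizerHit hf = rr.fwd_hit(ws), hr = rr.rev_hit(ws);
        start[ws - 1] = (double)ws;
        fmm[ws - 1] = decode_be((u128)hf.mmer, m);
        fpos[ws - 1] = hf.pos;
        rmm[ws - 1] = decode_be((u128)hr.mmer, m);
        rpos[ws - 1] = hr.pos;
    }
    return DataFrame::create(_["start"] = start, _["fwd_mmer"] = fmm, _["fwd_pos"] = fpos,
                             _["rc_mmer"] = rmm, _["rc_pos"] = rpos,
                             _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
DataFrame cpp_displace_canonical(std::string x, double j, int m, bool lex, double seed) {
    int k = (int)x.size();
    if (m < 1 || m > 31 || m >= k) stop("need 1 <= m < k and m <= 31");
    check_dna(x, "k-mer");
    u64 jj = as_u64(j, "j");
    if (jj < 1) stop("j must be >= 1");
    MinOrder O = make_order(m, lex, seed);
    u128 xf = encode_be(x);
    CanonicalHit h = cmini_code(xf, rc_be(xf, k), k, m, O);
    std::vector<Disp> ds;
    canonical_disps(h, k, m, ds);
    std::vector<double> qs; std::vector<int> os;
    for (const Disp& d : ds) {
        if ((u64)d.d > jj) continue; // candidate would start before position 1
        qs.push_back((double)(jj - (u64)d.d + 1));
        os.push_back(d.orient);
    }
    return DataFrame::create(_["q"] = NumericVector(qs.begin(), qs.end()),
                             _["orientation"] = IntegerVector(os.begin(), os.end()));
}

// ---------------------------------------------------------------- ef_sequence

// [[Rcpp::export]]
List cpp_ef_build(NumericVector a, double U) {
    std::vector<u64> A(a.size());
    for (R_xlen_t i = 0; i < a.size(); ++i) A[i] = as_u64(a[i], "array element");
    EliasFano ef;
    ef.build(A, as_u64(U, "U"));
    return List::create(_["n"] = (double)ef.n, _["U"] = (double)ef.U, _["l"] = ef.l,
                        _["low"] = words_to_raw(ef.l > 0 ? ef.low.words
                                                         : std::vector<u64>()),
                        _["high"] = words_to_raw(ef.high.words),
                        _["high_nbits"] = (double)ef.high.nbits);
}

static EliasFano ef_from_list(const List& e) {
    EliasFano ef;
    ef.n = as_u64(e["n"], "n");
    ef.U = as_u64(e["U"], "U");
    ef.l = as<int>(e["l"]);
    if (ef.l > 0) {
        ef.low.resize(ef.n, ef.l);
        std::vector<u64> lw = raw_to_words(e["low"]);
        std::copy(lw.begin(), lw.end(), ef.low.words.begin());
    }
    ef.high.nbits = as_u64(e["high_nbits"], "high_nbits");
    ef.high.words = raw_to_words(e["high"]);
    return ef;
}

// [[Rcpp::export]]
NumericVector cpp_ef_access(List e, NumericVector ii) {
    EliasFano ef = ef_from_list(e);
    NumericVector out(ii.size());
    for (R_xlen_t t = 0; t < ii.size(); ++t) {
        u64 i = as_u64(ii[t], "index");
        if (i < 1 || i > ef.n) stop("access index %d out of range 1..%d", (int)i, (int)ef.n);
        out[t] = (double)ef.access(i);
    }
    return out;
}

// [[Rcpp::export]]
List cpp_ef_successor(List e, NumericVector xx) {
    EliasFano ef = ef_from_list(e);
    NumericVector idx(xx.size()), val(xx.size());
    u64 last = ef.access(ef.n);
    for (R_xlen_t t = 0; t < xx.size(); ++t) {
        u64 x = as_u64(xx[t], "x");
        if (x > last)
            stop("successor argument %d exceeds the last element %d", (int)x, (int)last);
        std::pair<u64, u64> s = ef.successor(x);
        idx[t] = (double)s.first;
        val[t] = (double)s.second;
    }
    return List::create(_["index"] = idx, _["value"] = val);
}

// ---------------------------------------------------------------- mphf

// [[Rcpp::export]]
List cpp_mphf_build(NumericVector keys, double seed) {
    std::vector<u128> ks(keys.size());
    for (R_xlen_t i = 0; i < keys.size(); ++i) ks[i] = (u128)as_u64(keys[i], "key");
    Mphf f;
    f.build(ks, as_u64(seed, "seed"));
    Writer w;
    f.save(w);
    RawVector blob(w.buf.size());
    std::copy(w.buf.begin(), w.buf.end(), blob.begin());
    return List::create(_["blob"] = blob, _["M"] = (double)f.M,
                        _["n_buckets"] = (double)f.nbuck,
                        _["pilot_width"] = f.pilots.w,
                        _["size_bits"] = (double)f.size_bits(),
                        _["bits_per_key"] = f.bits_per_key());
}

// [[Rcpp::export]]
NumericVector cpp_mphf_eval(RawVector blob, NumericVector keys) {
    Reader r(RAW(blob), (size_t)blob.size());
    Mphf f;
    f.load(r);
    NumericVector out(keys.size());
    for (R_xlen_t i = 0; i < keys.size(); ++i)
        out[i] = (double)f.eval((u128)as_u64(keys[i], "key"));
    return out;
}

// ---------------------------------------------------------------- locate_layout

// Standalone layout over an explicit occurrence map (for inspection/tests):
// occ is a named list minimizer -> sorted positions; heavy is a named list
// minimizer -> list(kmers=, loc_index=) for minimizers with > 2^l positions.
// [[Rcpp::export]]
List cpp_build_layout(List occ, List heavy, int l, int r, double N, double seed,
                      bool canonical) {
    CharacterVector nm = occ.names();
    if (nm.size() != occ.size()) stop("occ must be a fully named list");
    u64 NN = as_u64(N, "N");
    int m = -1;
    std::vector<LocEntry> entries;
    for (R_xlen_t i = 0; i < occ.size(); ++i) {
        std::string mm = as<std::string>(nm[i]);
        if (m < 0) m = (int)mm.size();
        if ((int)mm.size() != m) stop("all minimizers must have equal length");
        check_dna(mm, "minimizer");
        LocEntry e;
        e.value = (u64)encode_be(mm);
        if (canonical) e.value = std::min(e.value, rc_be64(e.value, m));
        NumericVector ps = occ[i];
        for (R_xlen_t t = 0; t < ps.size(); ++t) {
            u64 p = as_u64(ps[t], "position");
            if (p < 1 || p + (u64)m - 1 > NN) stop("occurrence position out of range");
            e.pos.push_back(p);
        }
        std::sort(e.pos.begin(), e.pos.end());
        e.pos.erase(std::unique(e.pos.begin(), e.pos.end()), e.pos.end());
        entries.push_back(e);
    }
    std::sort(entries.begin(), entries.end(),
              [](const LocEntry& a, const LocEntry& b) { return a.value < b.value; });
    for (size_t i = 1; i < entries.size(); ++i)
        if (entries[i].value == entries[i - 1].value) stop("duplicate minimizer in occ");

    std::vector<HeavyKmer> hks;
    int kk = -1;
    if (heavy.size() > 0) {
        CharacterVector hn = heavy.names();
        for (R_xlen_t i = 0; i < heavy.size(); ++i) {
            std::string mm = as<std::string>(hn[i]);
            u64 value = (u64)encode_be(mm);
            if (canonical) value = std::min(value, rc_be64(value, m));
            List h = heavy[i];
            CharacterVector kms = h["kmers"];
            NumericVector li = h["loc_index"];
            if (kms.size() != li.size()) stop("kmers and loc_index lengths differ");
            for (R_xlen_t t = 0; t < kms.size(); ++t) {
                std::string x = as<std::string>(kms[t]);
                if (kk < 0) kk = (int)x.size();
                if ((int)x.size() != kk) stop("all heavy k-mers must have equal length");
                u128 key = encode_be(x);
                if (canonical) key = std::min(key, rc_be(key, kk));
                hks.push_back({key, value, as_u64(li[t], "loc_index") - 1});
            }
        }
    }
    std::vector<u128> mkeys(entries.size());
    for (size_t i = 0; i < entries.size(); ++i) mkeys[i] = (u128)entries[i].value;
    Mphf f;
    f.build(mkeys, splitmix64(as_u64(seed, "seed") ^ 0xF00DF00DULL));
    Layout lay;
    lay.build(entries, hks, f, l, r, NN, splitmix64(as_u64(seed, "seed") ^ 0xABCDEF987ULL));

    Writer w;
    w.put_u64((u64)m);
    w.put_u64(canonical ? 1 : 0);
    f.save(w);
    lay.save(w);
    RawVector blob(w.buf.size());
    std::copy(w.buf.begin(), w.buf.end(), blob.begin());

    NumericVector tags(lay.M);
    for (u64 t = 0; t < lay.M; ++t) tags[t] = (double)lay.T.get(t);
    return List::create(
        _["blob"] = blob, _["M"] = (double)lay.M, _["m"] = m,
        _["tag_width"] = lay.tagw, _["pos_width"] = lay.pw, _["widened"] = lay.widened,
        _["l"] = lay.l, _["r"] = lay.r, _["tags"] = tags,
        _["n_singleton"] = (double)lay.n_singleton, _["max_loc"] = (double)lay.maxloc,
        _["L_entries"] = (double)lay.L.n, _["H_entries"] = (double)lay.H.n,
        _["n_partitions"] = (int)lay.parts.size(),
        _["bits"] = List::create(_["T"] = (double)lay.bits_T(), _["L"] = (double)lay.bits_L(),
                                 _["H"] = (double)lay.bits_H(), _["G"] = (double)lay.bits_G(),
                                 _["skew"] = (double)lay.bits_skew()));
}

// [[Rcpp::export]]
List cpp_layout_locate(RawVector blob, std::string mmer, std::string kmer) {
    Reader r(RAW(blob), (size_t)blob.size());
    int m = (int)r.get_u64();
    bool canonical = r.get_u64() != 0;
    Mphf f;
    f.load(r);
    Layout lay;
    lay.load(r);
    if ((int)mmer.size() != m) stop("minimizer has wrong length");
    u64 value = (u64)encode_be(mmer);
    if (canonical) value = std::min(value, rc_be64(value, m));
    u128 kkey = 0;
    bool have_key = !kmer.empty();
    if (have_key) {
        u128 x = encode_be(kmer);
        kkey = canonical ? std::min(x, rc_be(x, (int)kmer.size())) : x;
    }
    ProbeCount pc;
    PackedSeq noS; // standalone layout carries no sequence: anchor checks skipped
    u64 t = f.eval((u128)value);
    LocateHit lh = lay.locate(t, value, kkey, have_key, noS, m, canonical, &pc);
    NumericVector cand(lh.candidates.size());
    for (size_t i = 0; i < lh.candidates.size(); ++i) cand[i] = (double)lh.candidates[i];
    return List::create(
        _["type"] = lh.type == 0 ? "singleton" : (lh.type == 1 ? "light" : "heavy"),
        _["tag_slot"] = (double)t, _["candidates"] = cand,
        _["probes"] = List::create(_["L"] = (double)pc.L, _["H"] = (double)pc.H,
                                   _["V"] = (double)pc.V, _["G"] = (double)pc.G));
}

// [[Rcpp::export]]
int cpp_skew_partition_of(double z, int l, int r) {
    u64 zz = as_u64(z, "z");
    if (zz <= (1ULL << l)) stop("z must exceed 2^l (heavy minimizers only)");
    return skew_partition_of(zz, l, r);
}

// ---------------------------------------------------------------- dictionary

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector strings, int k, int m, bool canonical, bool lex,
                     double seed, int l, int r) {
    Params p;
    p.k = k; p.m = m; p.canonical = canonical; p.lex = lex;
    p.seed = as_u64(seed, "seed"); p.l = l; p.r = r;
    Index* ix = new Index();
    try {
        ix->build(as_strings(strings), p);
    } catch (...) {
        delete ix;
        throw;
    }
    XPtr<Index> ptr(ix, true);
    return ptr;
}

static Index* get_index(SEXP p) {
    XPtr<Index> ptr(p);
    if (!ptr) stop("invalid index pointer (was the index saved and reloaded?)");
    return ptr.get();
}

// [[Rcpp::export]]
List cpp_index_info(SEXP p) {
    Index* ix = get_index(p);
    NumericVector psizes;
    CharacterVector pnames;
    for (const SkewPartition& sp : ix->lay.parts) {
        psizes.push_back((double)sp.V.n);
        pnames.push_back(std::to_string(sp.i));
    }
    psizes.attr("names") = pnames;
    return List::create(
        _["k"] = ix->par.k, _["m"] = ix->par.m, _["mode"] = ix->par.canonical ?
            "canonical" : "regular",
        _["order"] = ix->par.lex ? "lexicographic" : "random",
        _["seed"] = (double)ix->par.seed, _["l"] = ix->par.l, _["r"] = ix->par.r,
        _["n"] = (double)ix->n, _["N"] = (double)ix->N, _["n_strings"] = (double)ix->n_strings,
        _["M"] = (double)ix->M, _["Z"] = (double)ix->Z,
        _["n_super_kmers"] = (double)ix->n_super, _["alpha"] = (double)ix->alpha,
        _["beta"] = ix->beta(), _["max_loc"] = (double)ix->lay.maxloc,
        _["n_singleton"] = (double)ix->lay.n_singleton,
        _["tag_width"] = ix->lay.tagw, _["tag_widened"] = ix->lay.widened,
        _["mphf_bits_per_key"] = ix->f.bits_per_key(),
        _["partition_sizes"] = psizes);
}

// [[Rcpp::export]]
List cpp_lookup(SEXP p, CharacterVector kmers) {
    Index* ix = get_index(p);
    R_xlen_t n = kmers.size();
    NumericVector h(n), si(n), q(n);
    IntegerVector o(n);
    LogicalVector found(n);
    for (R_xlen_t t = 0; t < n; ++t) {
        LookupRes r = ix->lookup(as<std::string>(kmers[t]));
        found[t] = r.found;
        if (r.match) {
            h[t] = (double)r.h; si[t] = (double)r.i; q[t] = (double)r.q; o[t] = r.orient;
        } else {
            h[t] = NA_REAL; si[t] = NA_REAL; q[t] = NA_REAL; o[t] = NA_INTEGER;
        }
    }
    return List::create(_["handle"] = h, _["string_id"] = si, _["orientation"] = o,
                        _["position"] = q, _["found"] = found);
}

// [[Rcpp::export]]
CharacterVector cpp_access(SEXP p, NumericVector h) {
    Index* ix = get_index(p);
    CharacterVector out(h.size());
    for (R_xlen_t t = 0; t < h.size(); ++t) {
        double x = h[t];
        if (ISNA(x) || x < 1 || x != std::floor(x)) { out[t] = ""; continue; }
        out[t] = ix->access((u64)x);
    }
    return out;
}

// [[Rcpp::export]]
List cpp_space_report(SEXP p) {
    Index* ix = get_index(p);
    double sbits = 2.0 * (double)ix->N;
    double pbits = (double)ix->efP.size_bits();
    double fbits = (double)ix->f.size_bits();
    double tbits = (double)ix->lay.bits_T();
    double lbits = (double)ix->lay.bits_L();
    double hbits = (double)ix->lay.bits_H();
    double gbits = (double)ix->lay.bits_G();
    double kbits = (double)ix->lay.bits_skew();
    return List::create(
        _["component"] = CharacterVector::create("S", "P", "f", "T", "L", "H", "G", "skew"),
        _["bits"] = NumericVector::create(sbits, pbits, fbits, tbits, lbits, hbits,
                                          gbits, kbits));
}

// [[Rcpp::export]]
List cpp_save_index(SEXP p, std::string path) {
    Index* ix = get_index(p);
    Writer w;
    ix->save(w);
    // component boundaries, mirroring the layout of Index::save
    std::vector<double> sizes;
    std::vector<std::string> names;
    sizes.push_back(17.0 * 8);                   // magic + version + 14 fields + checksum
    names.push_back("header");
    Writer ws; ws.put_words(ix->S.words); ws.put_u64(0);
    names.push_back("S"); sizes.push_back((double)ws.buf.size());
    Writer wp; ix->efP.save(wp);
    names.push_back("P"); sizes.push_back((double)wp.buf.size());
    Writer wf; ix->f.save(wf);
    names.push_back("f"); sizes.push_back((double)wf.buf.size());
    Writer wl; ix->lay.save(wl);
    names.push_back("layout"); sizes.push_back((double)wl.buf.size());
    FILE* fp = fopen(path.c_str(), "wb");
    if (!fp) stop("cannot open '%s' for writing", path.c_str());
    size_t written = fwrite(w.buf.data(), 1, w.buf.size(), fp);
    fclose(fp);
    if (written != w.buf.size()) stop("short write to '%s'", path.c_str());
    return List::create(_["bytes"] = (double)w.buf.size(),
                        _["component"] = CharacterVector(names.begin(), names.end()),
                        _["component_bytes"] = NumericVector(sizes.begin(), sizes.end()));
}

// [[Rcpp::export]]
SEXP cpp_load_index(std::string path) {
    FILE* fp = fopen(path.c_str(), "rb");
    if (!fp) stop("cannot open '%s'", path.c_str());
    fseek(fp, 0, SEEK_END);
    long sz = ftell(fp);
    fseek(fp, 0, SEEK_SET);
    std::vector<unsigned char> buf((size_t)sz);
    size_t got = fread(buf.data(), 1, (size_t)sz, fp);
    fclose(fp);
    if (got != (size_t)sz) stop("short read from '%s'", path.c_str());
    Index* ix = new Index();
    try {
        Reader r(buf.data(), buf.size());
        ix->load(r);
    } catch (...) {
        delete ix;
        throw;
    }
    XPtr<Index> ptr(ix, true);
    return ptr;
}

// ---------------------------------------------------------------- stream_query

// [[Rcpp::export]]
List cpp_stream_lookup(SEXP p, CharacterVector reads, double budget) {
    Index* ix = get_index(p);
    long b0 = (long)as_u64(budget, "budget");
    std::vector<WindowOut> wins;
    std::vector<int> rid, wid;
    StreamStats st;
    for (R_xlen_t t = 0; t < reads.size(); ++t) {
        std::string rd = as<std::string>(reads[t]);
        std::vector<WindowOut> out1;
        stream_one_read(*ix, rd, b0, out1, st);
        for (size_t w = 0; w < out1.size(); ++w) {
            rid.push_back((int)(t + 1));
            wid.push_back((int)(w + 1));
            wins.push_back(out1[w]);
        }
    }
    R_xlen_t n = (R_xlen_t)wins.size();
    NumericVector h(n), si(n), q(n);
    IntegerVector o(n), method(n);
    LogicalVector found(n), valid(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        const WindowOut& wo = wins[i];
        valid[i] = wo.valid;
        found[i] = wo.found;
        method[i] = wo.method;
        if (wo.match) {
            h[i] = (double)wo.h; si[i] = (double)wo.i; q[i] = (double)wo.q; o[i] = wo.orient;
        } else {
            h[i] = NA_REAL; si[i] = NA_REAL; q[i] = NA_REAL; o[i] = NA_INTEGER;
        }
    }
    List stats = List::create(
        _["windows"] = (double)st.windows, _["positive"] = (double)st.positive,
        _["extensions"] = (double)st.extensions, _["seeds"] = (double)st.seeds,
        _["skipped"] = (double)st.skipped, _["invalid"] = (double)st.invalid,
        _["extension_rate"] = st.windows == 0 ? 0.0
                                              : (double)st.extensions / (double)st.windows);
    return List::create(_["read"] = IntegerVector(rid.begin(), rid.end()),
                        _["window"] = IntegerVector(wid.begin(), wid.end()),
                        _["handle"] = h, _["string_id"] = si, _["orientation"] = o,
                        _["position"] = q, _["found"] = found, _["valid"] = valid,
                        _["method"] = method, _["stats"] = stats);
}

// ---------------------------------------------------------------- synthetic data

// [[Rcpp::export]]
CharacterVector cpp_gen_spss(double total_bases, int n_strings, int k, double seed,
                             double rc_fraction) {
    std::vector<std::string> out = gen_spss(as_u64(total_bases, "total_bases"),
                                            (u64)n_strings, k, as_u64(seed, "seed"),
                                            rc_fraction);
    return CharacterVector(out.begin(), out.end());
}

// [[Rcpp::export]]
List cpp_gen_reads(CharacterVector strings, double n_reads, double read_length,
                   double sub_rate, double foreign_fraction, double rc_fraction,
                   double seed) {
    std::vector<std::string> reads;
    std::vector<ReadOrigin> origin;
    gen_reads(as_strings(strings), as_u64(n_reads, "n_reads"),
              as_u64(read_length, "read_length"), sub_rate, foreign_fraction,
              rc_fraction, as_u64(seed, "seed"), reads, origin);
    R_xlen_t n = (R_xlen_t)reads.size();
    NumericVector sid(n), start(n), nsub(n);
    LogicalVector rc(n), foreign(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        sid[i] = origin[i].string_id == 0 ? NA_REAL : (double)origin[i].string_id;
        start[i] = origin[i].string_id == 0 ? NA_REAL : (double)origin[i].start;
        nsub[i] = (double)origin[i].n_subs;
        rc[i] = origin[i].revcomp;
        foreign[i] = origin[i].string_id == 0;
    }
    return List::create(_["reads"] = CharacterVector(reads.begin(), reads.end()),
                        _["origin"] = DataFrame::create(
                            _["string_id"] = sid, _["start"] = start, _["revcomp"] = rc,
                            _["foreign"] = foreign, _["n_substitutions"] = nsub));
}

// [[Rcpp::export]]
LogicalVector cpp_kmer_membership(CharacterVector strings, int k, CharacterVector queries,
                                  bool canonical) {
    std::vector<bool> out = kmer_membership(as_strings(strings), k, as_strings(queries),
                                            canonical);
    return LogicalVector(out.begin(), out.end());
}

// [[Rcpp::export]]
DataFrame cpp_enumerate_kmers(CharacterVector strings, int k) {
    std::vector<std::string> ss = as_strings(strings);
    std::vector<std::string> km;
    std::vector<double> sid, pos;
    for (size_t i = 0; i < ss.size(); ++i) {
        if ((int)ss[i].size() < k) continue;
        for (size_t w = 0; w + k <= ss[i].size(); ++w) {
            km.push_back(ss[i].substr(w, k));
            sid.push_back((double)(i + 1));
            pos.push_back((double)(w + 1));
        }
    }
    return DataFrame::create(_["kmer"] = CharacterVector(km.begin(), km.end()),
                             _["string_id"] = NumericVector(sid.begin(), sid.end()),
                             _["position"] = NumericVector(pos.begin(), pos.end()),
                             _["stringsAsFactors"] = false);
}
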
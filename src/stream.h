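#ifndef KMERDICT_STREAM_H
#define KMERDICT_STREAM_H

// Budget-based streaming LOOKUP over reads.  The state of the last match
// (handle, string id, orientation, position, found flag, window minimizers)
// is carried across consecutive k-mer windows; while budget > 0 an extension
// (position shift by one in S) is attempted before re-seeding with a full
// lookup.  Windows whose minimizers equal those of the previous window are
// skipped without lookup when that window established the minimizer is
// absent from S.  Rolling minimizers are maintained in amortized O(1) per
// window with the re-scan method.

#include "index.h"

namespace kmerdict {

struct WindowOut {
    bool valid = true;   // false when the window contains a non-ACGT base
    bool match = false;
    bool found = false;
    u64 h = 0, i = 0, q = 0;
    int orient = 0;
    int method = 0;      // 0 seed, 1 extension, 2 negative skip, 3 invalid
};

struct StreamStats {
    u64 windows = 0, positive = 0, extensions = 0, seeds = 0, skipped = 0, invalid = 0;
};

struct StreamState {
    bool start = true;
    bool have_match = false;
    bool prev_found_f = false, prev_found_r = false;
    u64 prev_mmer_f = 0, prev_mmer_r = 0;
    bool have_prev_minis = false;
    u64 h = 0, i = 0, q = 0;
    int orient = 0;
    u64 pi = 0, pnext = 0;  // cached string bounds of i
    long budget = 0;
};

// Rolling window codes + two per-strand rolling minima over one read.
struct ReadRoller {
    const Index* ix;
    int k, m;
    MinOrder O;
    u128 mask2k, xf = 0, xr = 0;
    u64 mask2m, mmf = 0, mmr = 0;
    std::vector<u64> fcodes, rcodes; // m-mer codes by entry position (1-based)
    RollingMin minf, minr;
    long last_bad = 0;

    explicit ReadRoller(const Index* ix_) : ix(ix_) {
        k = ix->par.k; m = ix->par.m;
        O = ix->order();
        mask2k = ((((u128)1) << (2 * k)) - 1);
        mask2m = (m == 32) ? ~0ULL : ((1ULL << (2 * m)) - 1);
        minf.O = &O; minf.prefer_right = false;
        minr.O = &O; minr.prefer_right = true;
    }

    void feed(char c, long e) { // e: 1-based base position in the read
        int b = base_code(c);
        if (b < 0) { last_bad = e; b = 0; }
        xf = ((xf << 2) | (u128)b) & mask2k;
        xr = (xr >> 2) | ((u128)(3 - b) << (2 * (k - 1)));
        mmf = ((mmf << 2) | (u64)b) & mask2m;
        mmr = (mmr >> 2) | ((u64)(3 - b) << (2 * (m - 1)));
        if (e >= m) {
            long p = e - m + 1; // m-mer start position
            fcodes[(size_t)p] = mmf;
            rcodes[(size_t)p] = mmr;
        }
    }

    bool window_valid(long ws) const { return last_bad < ws; }

    // update rolling minima for window starting at ws (m-mers ws..ws+k-m)
    void roll(long ws, bool fresh) {
        long pe = ws + k - m;
        if (fresh) {
            minf.reset(); minr.reset();
            for (long p = ws; p <= pe; ++p) {
                minf.offer(fcodes[(size_t)p], p);
                minr.offer(rcodes[(size_t)p], p);
            }
            return;
        }
        if (minf.best_pos < ws) {
            minf.reset();
            for (long p = ws; p <= pe; ++p) minf.offer(fcodes[(size_t)p], p);
        } else {
            minf.offer(fcodes[(size_t)pe], pe);
        }
        if (minr.best_pos < ws) {
            minr.reset();
            for (long p = ws; p <= pe; ++p) minr.offer(rcodes[(size_t)p], p);
        } else {
            minr.offer(rcodes[(size_t)pe], pe);
        }
    }

    MinimizerHit fwd_hit(long ws) const {
        return {minf.best_code, (int)(minf.best_pos - ws + 1)};
    }
    MinimizerHit rev_hit(long ws) const {
        // position of the reverse-strand minimizer within rc(window)
        return {minr.best_code, rc_position(k, m, (int)(minr.best_pos - ws + 1))};
    }
};

inline void stream_one_read(const Index& ix, const std::string& read, long budget0,
                            std::vector<WindowOut>& out, StreamStats& st) {
    const int k = ix.par.k, m = ix.par.m;
    long len = (long)read.size();
    if (len < k) throw std::runtime_error("read shorter than k");
    long nw = len - k + 1;
    ReadRoller rr(&ix);
    rr.fcodes.assign((size_t)(len + 2), 0);
    rr.rcodes.assign((size_t)(len + 2), 0);
    StreamState stt;
    stt.start = true;
    stt.budget = budget0;
    for (long e = 1; e < k; ++e) rr.feed(read[(size_t)(e - 1)], e);
    for (long ws = 1; ws <= nw; ++ws) {
        rr.feed(read[(size_t)(ws + k - 2)], ws + k - 1);
        ++st.windows;
        WindowOut wo;
        if (!rr.window_valid(ws)) {
            wo.valid = false; wo.method = 3;
            ++st.invalid;
            stt.start = true; stt.have_match = false; stt.have_prev_minis = false;
            out.push_back(wo);
            continue;
        }
        rr.roll(ws, stt.start);
        MinimizerHit hf = rr.fwd_hit(ws), hr = rr.rev_hit(ws);

        // (b) extension while budget lasts
        if (!stt.start && stt.have_match && stt.budget > 0) {
            bool ok = false;
            u64 qn = 0;
            if (stt.orient > 0) {
                qn = stt.q + 1;
                if (qn + (u64)k <= stt.pnext && ix.S.extract_be(qn, k) == rr.xf) ok = true;
            } else {
                if (stt.q > stt.pi) {
                    qn = stt.q - 1;
                    if (ix.S.extract_be(qn, k) == rr.xr) ok = true;
                }
            }
            if (ok) {
                stt.q = qn;
                stt.h = ix.handle_of(qn, stt.i);
                --stt.budget;
                wo.match = true; wo.found = true;
                wo.h = stt.h; wo.i = stt.i; wo.q = stt.q; wo.orient = stt.orient;
                wo.method = 1;
                ++st.extensions; ++st.positive;
                out.push_back(wo);
                stt.start = false;
                stt.prev_mmer_f = hf.mmer; stt.prev_mmer_r = hr.mmer;
                stt.have_prev_minis = true;
                stt.prev_found_f = true; stt.prev_found_r = true; // match implies present
                continue;
            }
        }

        // (c) negative skip: same minimizers as previous window, which proved
        // the minimizer(s) absent from S
        bool can_skip = false;
        if (!stt.start && stt.have_prev_minis) {
            if (ix.par.canonical) {
                can_skip = !stt.prev_found_f && hf.mmer == stt.prev_mmer_f &&
                           hr.mmer == stt.prev_mmer_r;
            } else {
                can_skip = !stt.prev_found_f && !stt.prev_found_r &&
                           hf.mmer == stt.prev_mmer_f && hr.mmer == stt.prev_mmer_r;
            }
        }
        if (can_skip) {
            wo.match = false; wo.found = false; wo.method = 2;
            ++st.skipped;
            out.push_back(wo);
            stt.start = false;
            stt.prev_mmer_f = hf.mmer; stt.prev_mmer_r = hr.mmer;
            stt.have_prev_minis = true;
            continue;
        }

        // (d) Seed: full lookup, reset budget
        LookupRes res = lookup_with_hits(ix, rr.xf, rr.xr, hf, hr);
        ++st.seeds;
        stt.budget = budget0;
        wo.match = res.match; wo.found = res.found;
        wo.h = res.h; wo.i = res.i; wo.q = res.q; wo.orient = res.orient;
        wo.method = 0;
        if (res.match) {
            ++st.positive;
            stt.have_match = true;
            stt.h = res.h; stt.i = res.i; stt.q = res.q; stt.orient = res.orient;
            stt.pi = ix.P[res.i - 1];
            stt.pnext = ix.P[res.i];
        } else {
            stt.have_match = false;
        }
        stt.prev_found_f = res.found_f;
        stt.prev_found_r = res.found_r;
        stt.prev_mmer_f = hf.mmer; stt.prev_mmer_r = hr.mmer;
        stt.have_prev_minis = true;
        stt.start = false;
        out.push_back(wo);
    }
}

} // namespace kmerdict

#endif
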
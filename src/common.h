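#ifndef KMERDICT_COMMON_H
#define KMERDICT_COMMON_H

#include <cstdint>
#include <cstring>
#include <string>
#include <vector>
#include <stdexcept>
#include <algorithm>

namespace kmerdict {

typedef uint64_t u64;
typedef unsigned __int128 u128;

// Finalizer-style 64-bit mixer; all hashing in the package derives from it.
inline u64 splitmix64(u64 x) {
    x += 0x9E3779B97F4A7C15ULL;
    x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
    x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
    return x ^ (x >> 31);
}

inline u64 hash_u64(u64 x, u64 seed) { return splitmix64(x ^ splitmix64(seed)); }

inline u64 hash_u128(u128 x, u64 seed) {
    u64 lo = (u64)x, hi = (u64)(x >> 64);
    return splitmix64(lo ^ splitmix64(hi ^ splitmix64(seed)));
}

// Smallest width (>= 1) able to store any value in [0 .. maxval].
inline int bits_needed(u64 maxval) {
    int w = 1;
    while (w < 64 && (maxval >> w) != 0) ++w;
    return w;
}

// Deterministic, implementation-independent RNG (xorshift-style via splitmix).
struct Rng {
    u64 state;
    explicit Rng(u64 seed) : state(splitmix64(seed ^ 0xA5A5A5A5DEADBEEFULL)) {}
    u64 next() { state = splitmix64(state); return state; }
    // bounded draw in [0, n); modulo bias is irrelevant at simulation scale
    u64 below(u64 n) { return next() % n; }
    double unif() { return (double)(next() >> 11) * (1.0 / 9007199254740992.0); }
};

// Plain bit vector.
struct BitVec {
    u64 nbits = 0;
    std::vector<u64> words;
    void resize(u64 nb) { nbits = nb; words.assign((nb + 63) / 64, 0); }
    void set(u64 i) { words[i >> 6] |= 1ULL << (i & 63); }
    bool get(u64 i) const { return (words[i >> 6] >> (i & 63)) & 1; }
};

// Fixed-width packed integer vector (widths 1..64).
struct IntVec {
    int w = 1;
    u64 n = 0;
    std::vector<u64> words;

    IntVec() {}
    IntVec(u64 n_, int w_) { resize(n_, w_); }

    void resize(u64 n_, int w_) {
        if (w_ < 1) w_ = 1;
        if (w_ > 64) throw std::runtime_error("IntVec width > 64");
        w = w_; n = n_;
        words.assign((n * (u64)w + 63) / 64 + 1, 0); // +1 pad word for cross-word access
    }
    u64 mask() const { return w == 64 ? ~0ULL : ((1ULL << w) - 1); }
    void set(u64 i, u64 v) {
        u64 b = i * (u64)w;
        u64 wi = b >> 6;
        int off = (int)(b & 63);
        words[wi] = (words[wi] & ~(mask() << off)) | ((v & mask()) << off);
        if (off + w > 64) {
            int hi = off + w - 64;
            u64 him = (1ULL << hi) - 1;
            words[wi + 1] = (words[wi + 1] & ~him) | ((v & mask()) >> (64 - off));
        }
    }
    u64 get(u64 i) const {
        u64 b = i * (u64)w;
        u64 wi = b >> 6;
        int off = (int)(b & 63);
        u64 v = words[wi] >> off;
        if (off + w > 64) v |= words[wi + 1] << (64 - off);
        return v & mask();
    }
    u64 bits() const { return n * (u64)w; }
};

// Minimal binary (de)serialization helpers: little-endian u64 stream.
struct Writer {
    std::vector<unsigned char> buf;
    void put_u64(u64 v) {
        for (int i = 0; i < 8; ++i) buf.push_back((unsigned char)((v >> (8 * i)) & 0xFF));
    }
    void put_words(const std::vector<u64>& ws) {
        put_u64(ws.size());
        for (u64 w : ws) put_u64(w);
    }
    size_t pos() const { return buf.size(); }
};

struct Reader {
    const unsigned char* p;
    size_t len, off = 0;
    Reader(const unsigned char* p_, size_t len_) : p(p_), len(len_) {}
    u64 get_u64() {
        if (off + 8 > len) throw std::runtime_error("index file truncated");
        u64 v = 0;
        for (int i = 0; i < 8; ++i) v |= (u64)p[off + i] << (8 * i);
        off += 8;
        return v;
    }
    void get_words(std::vector<u64>& ws) {
        u64 nw = get_u64();
        if (off + 8 * nw > len) throw std::runtime_error("index file truncated");
        ws.resize(nw);
        for (u64 i = 0; i < nw; ++i) ws[i] = get_u64();
    }
};

} // namespace kmerdict

#endif
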
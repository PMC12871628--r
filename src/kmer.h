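#ifndef KMERDICT_KMER_H
#define KMERDICT_KMER_H

// DNA alphabet handling, 2-bit codes and the packed SPSS concatenation.
//
// Two integer encodings of a DNA string appear in the package:
//  * LE ("little-endian"): base at position 1 occupies the least significant
//    2-bit pair.  This is the public codec contract (encode_kmer).
//  * BE ("big-endian"): base at position 1 is most significant, so that for
//    equal lengths numeric order equals lexicographic order (A<C<G<T).  All
//    internal minimizer comparisons use BE codes.

#include "common.h"

namespace kmerdict {

inline int base_code(char c) {
    switch (c) {
        case 'A': case 'a': return 0;
        case 'C': case 'c': return 1;
        case 'G': case 'g': return 2;
        case 'T': case 't': return 3;
    }
    return -1;
}

inline char base_char(int b) { return "ACGT"[b & 3]; }

// Throws with the 1-based position of the first offending symbol.
inline void check_dna(const std::string& s, const char* what) {
    for (size_t i = 0; i < s.size(); ++i) {
        if (base_code(s[i]) < 0)
            throw std::runtime_error(std::string(what) + ": non-ACGT character '" +
                                     std::string(1, s[i]) + "' at position " +
                                     std::to_string(i + 1));
    }
}

inline u128 encode_be(const std::string& s) {
    u128 c = 0;
    for (char ch : s) {
        int b = base_code(ch);
        if (b < 0) throw std::runtime_error("non-ACGT character in k-mer");
        c = (c << 2) | (u128)b;
    }
    return c;
}

inline std::string decode_be(u128 c, int k) {
    std::string s((size_t)k, 'A');
    for (int p = k - 1; p >= 0; --p) {
        s[(size_t)p] = base_char((int)(c & 3));
        c >>= 2;
    }
    return s;
}

inline u128 le_from_be(u128 be, int k) {
    u128 le = 0;
    for (int i = 0; i < k; ++i) { le = (le << 2) | (be & 3); be >>= 2; }
    return le;
}

// Reverse complement on BE codes (works for any length <= 63).
inline u128 rc_be(u128 c, int k) {
    u128 r = 0;
    for (int i = 0; i < k; ++i) {
        r = (r << 2) | (u128)(3 - (int)(c & 3));
        c >>= 2;
    }
    return r;
}

inline u64 rc_be64(u64 c, int m) {
    u64 r = 0;
    for (int i = 0; i < m; ++i) { r = (r << 2) | (u64)(3 - (int)(c & 3)); c >>= 2; }
    return r;
}

inline std::string rc_string(const std::string& s) {
    std::string r(s.size(), 'A');
    for (size_t i = 0; i < s.size(); ++i) {
        int b = base_code(s[s.size() - 1 - i]);
        if (b < 0) throw std::runtime_error("non-ACGT character at position " +
                                            std::to_string(s.size() - i));
        r[i] = base_char(3 - b);
    }
    return r;
}

inline std::string u128_to_dec(u128 x) {
    if (x == 0) return "0";
    std::string s;
    while (x > 0) { s.push_back((char)('0' + (int)(x % 10))); x /= 10; }
    std::reverse(s.begin(), s.end());
    return s;
}

inline u128 dec_to_u128(const std::string& s) {
    u128 x = 0;
    for (char c : s) {
        if (c < '0' || c > '9') throw std::runtime_error("invalid decimal code string");
        x = x * 10 + (u128)(c - '0');
    }
    return x;
}

// 2-bit packed concatenation S[1..N]; base j occupies bits [2(j-1), 2j).
struct PackedSeq {
    u64 N = 0;
    std::vector<u64> words;

    void reserve_bases(u64 n) { words.assign((2 * n + 63) / 64 + 1, 0); N = 0; }
    void push(int b) {
        u64 bit = 2 * N;
        words[bit >> 6] |= ((u64)(b & 3)) << (bit & 63);
        ++N;
    }
    int get(u64 j) const { // 1-based
        u64 bit = 2 * (j - 1);
        return (int)((words[bit >> 6] >> (bit & 63)) & 3);
    }
    u128 extract_be(u64 q, int w) const {
        u128 c = 0;
        for (int t = 0; t < w; ++t) c = (c << 2) | (u128)get(q + t);
        return c;
    }
    u64 extract_be64(u64 q, int w) const {
        u64 c = 0;
        for (int t = 0; t < w; ++t) c = (c << 2) | (u64)get(q + t);
        return c;
    }
    std::string extract_str(u64 q, int w) const {
        std::string s((size_t)w, 'A');
        for (int t = 0; t < w; ++t) s[(size_t)t] = base_char(get(q + t));
        return s;
    }
};

} // namespace kmerdict

#endif
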
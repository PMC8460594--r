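#ifndef TREEURN_BIGNUM_H
#define TREEURN_BIGNUM_H

// Minimal arbitrary-precision natural numbers and signed rationals.
// Little-endian base 2^32 limbs.  Only the operations the exact DP needs:
// add, subtract, schoolbook multiply, binary gcd, shift-subtract division
// (division is used once per reported quantity, never in the DP loop).

#include <vector>
#include <cstdint>
#include <cstdio>
#include <string>
#include <cmath>
#include <algorithm>
#include <stdexcept>

struct BigNat {
    std::vector<uint32_t> d; // empty == 0
    BigNat() {}
    explicit BigNat(uint64_t v) {
        if (v) {
            d.push_back(static_cast<uint32_t>(v));
            if (v >> 32) d.push_back(static_cast<uint32_t>(v >> 32));
        }
    }
    bool is_zero() const { return d.empty(); }
    void trim() { while (!d.empty() && d.back() == 0) d.pop_back(); }
};

inline int bn_cmp(const BigNat& a, const BigNat& b) {
    if (a.d.size() != b.d.size()) return a.d.size() < b.d.size() ? -1 : 1;
    for (size_t i = a.d.size(); i-- > 0;)
        if (a.d[i] != b.d[i]) return a.d[i] < b.d[i] ? -1 : 1;
    return 0;
}

inline BigNat bn_add(const BigNat& a, const BigNat& b) {
    BigNat r;
    const size_t n = std::max(a.d.size(), b.d.size());
    r.d.resize(n, 0);
    uint64_t carry = 0;
    for (size_t i = 0; i < n; ++i) {
        uint64_t s = carry;
        if (i < a.d.size()) s += a.d[i];
        if (i < b.d.size()) s += b.d[i];
        r.d[i] = static_cast<uint32_t>(s);
        carry = s >> 32;
    }
    if (carry) r.d.push_back(static_cast<uint32_t>(carry));
    return r;
}

inline void bn_add_inplace(BigNat& a, const BigNat& b) { a = bn_add(a, b); }

// a - b; requires a >= b
inline BigNat bn_sub(const BigNat& a, const BigNat& b) {
    BigNat r;
    r.d.resize(a.d.size(), 0);
    int64_t borrow = 0;
    for (size_t i = 0; i < a.d.size(); ++i) {
        int64_t s = static_cast<int64_t>(a.d[i]) - borrow -
                    (i < b.d.size() ? static_cast<int64_t>(b.d[i]) : 0);
        if (s < 0) { s += (static_cast<int64_t>(1) << 32); borrow = 1; }
        else borrow = 0;
        r.d[i] = static_cast<uint32_t>(s);
    }
    r.trim();
    return r;
}

inline BigNat bn_mul(const BigNat& a, const BigNat& b) {
    BigNat r;
    if (a.is_zero() || b.is_zero()) return r;
    r.d.assign(a.d.size() + b.d.size(), 0);
    for (size_t i = 0; i < a.d.size(); ++i) {
        uint64_t carry = 0;
        const uint64_t ai = a.d[i];
        for (size_t j = 0; j < b.d.size(); ++j) {
            uint64_t cur = r.d[i + j] + ai * b.d[j] + carry;
            r.d[i + j] = static_cast<uint32_t>(cur);
            carry = cur >> 32;
        }
        size_t k = i + b.d.size();
        while (carry) {
            uint64_t cur = r.d[k] + carry;
            r.d[k] = static_cast<uint32_t>(cur);
            carry = cur >> 32;
            ++k;
        }
    }
    r.trim();
    return r;
}

inline size_t bn_bitlen(const BigNat& a) {
    if (a.is_zero()) return 0;
    size_t bits = (a.d.size() - 1) * 32;
    uint32_t top = a.d.back();
    while (top) { ++bits; top >>= 1; }
    return bits;
}

inline BigNat bn_shl(const BigNat& a, size_t bits) {
    if (a.is_zero() || bits == 0) return a;
    const size_t limb = bits / 32, off = bits % 32;
    BigNat r;
    r.d.assign(a.d.size() + limb + 1, 0);
    for (size_t i = 0; i < a.d.size(); ++i) {
        uint64_t v = static_cast<uint64_t>(a.d[i]) << off;
        r.d[i + limb] |= static_cast<uint32_t>(v);
        r.d[i + limb + 1] |= static_cast<uint32_t>(v >> 32);
    }
    r.trim();
    return r;
}

inline BigNat bn_shr(const BigNat& a, size_t bits) {
    const size_t limb = bits / 32, off = bits % 32;
    if (limb >= a.d.size()) return BigNat();
    BigNat r;
    r.d.assign(a.d.size() - limb, 0);
    for (size_t i = 0; i < r.d.size(); ++i) {
        uint64_t v = a.d[i + limb] >> off;
        if (off && i + limb + 1 < a.d.size())
            v |= static_cast<uint64_t>(a.d[i + limb + 1]) << (32 - off);
        r.d[i] = static_cast<uint32_t>(v);
    }
    r.trim();
    return r;
}

inline void bn_shr1(BigNat& a) { a = bn_shr(a, 1); }
inline bool bn_even(const BigNat& a) { return a.is_zero() || (a.d[0] & 1u) == 0; }

// quotient and remainder by shift-subtract; b must be nonzero
inline void bn_divmod(const BigNat& a, const BigNat& b, BigNat& q, BigNat& r) {
    if (b.is_zero()) throw std::runtime_error("bignum division by zero");
    q = BigNat();
    r = a;
    if (bn_cmp(a, b) < 0) return;
    const size_t shift = bn_bitlen(a) - bn_bitlen(b);
    BigNat bs = bn_shl(b, shift);
    q.d.assign(shift / 32 + 1, 0);
    for (size_t i = shift + 1; i-- > 0;) {
        if (bn_cmp(r, bs) >= 0) {
            r = bn_sub(r, bs);
            q.d[i / 32] |= (static_cast<uint32_t>(1) << (i % 32));
        }
        bn_shr1(bs);
    }
    q.trim();
}

inline BigNat bn_div_exact(const BigNat& a, const BigNat& b) {
    BigNat q, r;
    bn_divmod(a, b, q, r);
    return q;
}

inline BigNat bn_gcd(BigNat a, BigNat b) {
    if (a.is_zero()) return b;
    if (b.is_zero()) return a;
    size_t k = 0;
    while (bn_even(a) && bn_even(b)) { bn_shr1(a); bn_shr1(b); ++k; }
    while (bn_even(a)) bn_shr1(a);
    while (!b.is_zero()) {
        while (bn_even(b)) bn_shr1(b);
        if (bn_cmp(a, b) > 0) std::swap(a, b);
        b = bn_sub(b, a);
    }
    return bn_shl(a, k);
}

// divide a by small m in place, return remainder
inline uint32_t bn_divmod_small(BigNat& a, uint32_t m) {
    uint64_t rem = 0;
    for (size_t i = a.d.size(); i-- > 0;) {
        uint64_t cur = (rem << 32) | a.d[i];
        a.d[i] = static_cast<uint32_t>(cur / m);
        rem = cur % m;
    }
    a.trim();
    return static_cast<uint32_t>(rem);
}

inline std::string bn_to_string(BigNat a) {
    if (a.is_zero()) return "0";
    std::vector<uint32_t> chunks;
    while (!a.is_zero()) chunks.push_back(bn_divmod_small(a, 1000000000u));
    std::string out = std::to_string(chunks.back());
    char buf[16];
    for (size_t i = chunks.size() - 1; i-- > 0;) {
        std::snprintf(buf, sizeof(buf), "%09u", chunks[i]);
        out += buf;
    }
    return out;
}

inline double bn_to_double(const BigNat& a) {
    double r = 0;
    for (size_t i = a.d.size(); i-- > 0;) r = r * 4294967296.0 + a.d[i];
    return r;
}

// num/den as a double, robust against overflow of either operand
inline double bn_ratio(const BigNat& num, const BigNat& den) {
    if (num.is_zero()) return 0.0;
    const long bn = static_cast<long>(bn_bitlen(num));
    const long bd = static_cast<long>(bn_bitlen(den));
    const long dn = std::max(0L, bn - 64), dd = std::max(0L, bd - 64);
    const double top_n = bn_to_double(bn_shr(num, static_cast<size_t>(dn)));
    const double top_d = bn_to_double(bn_shr(den, static_cast<size_t>(dd)));
    return (top_n / top_d) * std::pow(2.0, static_cast<double>(dn - dd));
}

// Signed rationals ------------------------------------------------------

struct BigRat {
    int sign;    // -1, 0, 1
    BigNat num;  // |numerator|
    BigNat den;  // > 0
    BigRat() : sign(0), den(BigNat(1)) {}
};

inline BigRat rat_make(int sign, BigNat num, BigNat den) {
    BigRat r;
    if (num.is_zero()) { r.sign = 0; r.num = BigNat(); r.den = BigNat(1); return r; }
    BigNat g = bn_gcd(num, den);
    r.sign = sign;
    r.num = bn_div_exact(num, g);
    r.den = bn_div_exact(den, g);
    return r;
}

inline BigRat rat_mul(const BigRat& a, const BigRat& b) {
    if (a.sign == 0 || b.sign == 0) return BigRat();
    return rat_make(a.sign * b.sign, bn_mul(a.num, b.num), bn_mul(a.den, b.den));
}

inline BigRat rat_add(const BigRat& a, const BigRat& b) {
    if (a.sign == 0) return b;
    if (b.sign == 0) return a;
    BigNat x = bn_mul(a.num, b.den);
    BigNat y = bn_mul(b.num, a.den);
    BigNat den = bn_mul(a.den, b.den);
    if (a.sign == b.sign) return rat_make(a.sign, bn_add(x, y), den);
    const int c = bn_cmp(x, y);
    if (c == 0) return BigRat();
    if (c > 0) return rat_make(a.sign, bn_sub(x, y), den);
    return rat_make(b.sign, bn_sub(y, x), den);
}

inline BigRat rat_neg(const BigRat& a) {
    BigRat r = a;
    r.sign = -r.sign;
    return r;
}

inline BigRat rat_sub(const BigRat& a, const BigRat& b) { return rat_add(a, rat_neg(b)); }

inline std::string rat_to_string(const BigRat& a) {
    if (a.sign == 0) return "0";
    std::string s = (a.sign < 0 ? "-" : "") + bn_to_string(a.num);
    if (!(a.den.d.size() == 1 && a.den.d[0] == 1)) s += "/" + bn_to_string(a.den);
    return s;
}

inline double rat_to_double(const BigRat& a) {
    if (a.sign == 0) return 0.0;
    return a.sign * bn_ratio(a.num, a.den);
}

#endif
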
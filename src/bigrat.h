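// Arbitrary-precision signed integers and exact rationals.
//
// The closed formulas evaluated by this package dispatch on exact equalities
// (a == 2^{t+l}, vanishing denominators 2^{t+l} - a) and reach magnitudes far
// beyond 2^53, so all arithmetic is exact rational with arbitrary-precision
// numerators/denominators.  Limbs are base 2^32; schoolbook algorithms are
// ample for the ~40-digit numbers that occur here.
#ifndef HALFREC_BIGRAT_H
#define HALFREC_BIGRAT_H

#include <vector>
#include <string>
#include <cstdint>
#include <cstdio>
#include <stdexcept>
#include <algorithm>

namespace hr {

typedef uint32_t limb_t;
typedef uint64_t dlimb_t;

inline void trim(std::vector<limb_t> &d) {
  while (!d.empty() && d.back() == 0) d.pop_back();
}

inline int cmp_mag(const std::vector<limb_t> &a, const std::vector<limb_t> &b) {
  if (a.size() != b.size()) return a.size() < b.size() ? -1 : 1;
  for (size_t i = a.size(); i-- > 0;) {
    if (a[i] != b[i]) return a[i] < b[i] ? -1 : 1;
  }
  return 0;
}

inline std::vector<limb_t> add_mag(const std::vector<limb_t> &a,
                                   const std::vector<limb_t> &b) {
  const std::vector<limb_t> &x = a.size() >= b.size() ? a : b;
  const std::vector<limb_t> &y = a.size() >= b.size() ? b : a;
  std::vector<limb_t> r(x.size() + 1, 0);
  dlimb_t carry = 0;
  for (size_t i = 0; i < x.size(); ++i) {
    dlimb_t cur = carry + x[i] + (i < y.size() ? y[i] : 0);
    r[i] = (limb_t)cur;
    carry = cur >> 32;
  }
  r[x.size()] = (limb_t)carry;
  trim(r);
  return r;
}

// requires a >= b
inline std::vector<limb_t> sub_mag(const std::vector<limb_t> &a,
                                   const std::vector<limb_t> &b) {
  std::vector<limb_t> r(a.size(), 0);
  int64_t borrow = 0;
  for (size_t i = 0; i < a.size(); ++i) {
    int64_t cur = (int64_t)a[i] - (i < b.size() ? (int64_t)b[i] : 0) - borrow;
    if (cur < 0) { cur += ((int64_t)1 << 32); borrow = 1; } else borrow = 0;
    r[i] = (limb_t)cur;
  }
  trim(r);
  return r;
}

inline std::vector<limb_t> mul_mag(const std::vector<limb_t> &a,
                                   const std::vector<limb_t> &b) {
  if (a.empty() || b.empty()) return std::vector<limb_t>();
  std::vector<limb_t> r(a.size() + b.size(), 0);
  for (size_t i = 0; i < a.size(); ++i) {
    dlimb_t carry = 0;
    for (size_t j = 0; j < b.size(); ++j) {
      dlimb_t cur = r[i + j] + (dlimb_t)a[i] * b[j] + carry;
      r[i + j] = (limb_t)cur;
      carry = cur >> 32;
    }
    r[i + b.size()] = (limb_t)carry;
  }
  trim(r);
  return r;
}

// divide by a 64-bit divisor; quotient limbs stay < 2^32 because rem < div
inline std::vector<limb_t> divmod_u64(const std::vector<limb_t> &a,
                                      dlimb_t div, dlimb_t &rem) {
  std::vector<limb_t> q(a.size(), 0);
  __uint128_t r = 0;
  for (size_t i = a.size(); i-- > 0;) {
    __uint128_t cur = (r << 32) | a[i];
    q[i] = (limb_t)(cur / div);
    r = cur % div;
  }
  rem = (dlimb_t)r;
  trim(q);
  return q;
}

inline size_t bitlen_mag(const std::vector<limb_t> &a) {
  if (a.empty()) return 0;
  size_t b = 32 * (a.size() - 1);
  limb_t t = a.back();
  while (t) { ++b; t >>= 1; }
  return b;
}

inline bool getbit(const std::vector<limb_t> &a, size_t i) {
  size_t w = i / 32;
  return w < a.size() && ((a[w] >> (i % 32)) & 1u);
}

inline void shl1_inplace(std::vector<limb_t> &a) {
  limb_t carry = 0;
  for (size_t i = 0; i < a.size(); ++i) {
    limb_t nc = a[i] >> 31;
    a[i] = (a[i] << 1) | carry;
    carry = nc;
  }
  if (carry) a.push_back(carry);
}

inline void shr1_inplace(std::vector<limb_t> &a) {
  for (size_t i = 0; i < a.size(); ++i) {
    a[i] >>= 1;
    if (i + 1 < a.size() && (a[i + 1] & 1u)) a[i] |= 0x80000000u;
  }
  trim(a);
}

// general long division (bit-serial); only hit when the divisor exceeds 64 bits
inline std::vector<limb_t> divmod_mag(const std::vector<limb_t> &a,
                                      const std::vector<limb_t> &b,
                                      std::vector<limb_t> &rem) {
  if (b.empty()) throw std::runtime_error("division by zero");
  if (b.size() <= 2) {
    dlimb_t div = b[0] | (b.size() == 2 ? ((dlimb_t)b[1] << 32) : 0);
    dlimb_t r64 = 0;
    std::vector<limb_t> q = divmod_u64(a, div, r64);
    rem.clear();
    if (r64) { rem.push_back((limb_t)r64); if (r64 >> 32) rem.push_back((limb_t)(r64 >> 32)); }
    return q;
  }
  std::vector<limb_t> q((a.size()), 0), r;
  size_t nb = bitlen_mag(a);
  for (size_t i = nb; i-- > 0;) {
    shl1_inplace(r);
    if (getbit(a, i)) { if (r.empty()) r.push_back(1); else r[0] |= 1u; }
    if (cmp_mag(r, b) >= 0) {
      r = sub_mag(r, b);
      q[i / 32] |= (1u << (i % 32));
    }
  }
  trim(q);
  rem = r;
  return q;
}

inline std::vector<limb_t> gcd_mag(std::vector<limb_t> a, std::vector<limb_t> b) {
  if (a.empty()) return b;
  if (b.empty()) return a;
  size_t shift = 0;
  while (!getbit(a, 0) && !getbit(b, 0)) { shr1_inplace(a); shr1_inplace(b); ++shift; }
  while (!a.empty() && !getbit(a, 0)) shr1_inplace(a);
  while (true) {
    while (!b.empty() && !getbit(b, 0)) shr1_inplace(b);
    if (b.empty()) break;
    if (cmp_mag(a, b) > 0) std::swap(a, b);
    b = sub_mag(b, a);
  }
  for (size_t i = 0; i < shift; ++i) shl1_inplace(a);
  return a;
}

struct BigInt {
  int sign;                    // -1, 0, +1
  std::vector<limb_t> mag;

  BigInt() : sign(0) {}
  BigInt(long long v) : sign(0) {
    if (v == 0) return;
    sign = v < 0 ? -1 : 1;
    unsigned long long u = v < 0 ? -(unsigned long long)v : (unsigned long long)v;
    mag.push_back((limb_t)u);
    if (u >> 32) mag.push_back((limb_t)(u >> 32));
  }

  bool is_zero() const { return sign == 0; }
  bool is_one() const { return sign == 1 && mag.size() == 1 && mag[0] == 1; }

  static int cmp(const BigInt &a, const BigInt &b) {
    if (a.sign != b.sign) return a.sign < b.sign ? -1 : 1;
    int c = cmp_mag(a.mag, b.mag);
    return a.sign >= 0 ? c : -c;
  }
  bool operator==(const BigInt &o) const { return cmp(*this, o) == 0; }

  BigInt neg() const { BigInt r = *this; r.sign = -r.sign; return r; }

  static BigInt add(const BigInt &a, const BigInt &b) {
    if (a.sign == 0) return b;
    if (b.sign == 0) return a;
    BigInt r;
    if (a.sign == b.sign) {
      r.sign = a.sign;
      r.mag = add_mag(a.mag, b.mag);
    } else {
      int c = cmp_mag(a.mag, b.mag);
      if (c == 0) return BigInt();
      if (c > 0) { r.sign = a.sign; r.mag = sub_mag(a.mag, b.mag); }
      else       { r.sign = b.sign; r.mag = sub_mag(b.mag, a.mag); }
    }
    return r;
  }
  static BigInt sub(const BigInt &a, const BigInt &b) { return add(a, b.neg()); }
  static BigInt mul(const BigInt &a, const BigInt &b) {
    BigInt r;
    if (a.sign == 0 || b.sign == 0) return r;
    r.sign = a.sign * b.sign;
    r.mag = mul_mag(a.mag, b.mag);
    return r;
  }

  // exact division by a known divisor of *this (magnitudes)
  static BigInt div_exact(const BigInt &a, const std::vector<limb_t> &g) {
    if (a.sign == 0) return BigInt();
    BigInt r;
    r.sign = a.sign;
    if (g.size() <= 2) {
      dlimb_t d = g[0] | (g.size() == 2 ? ((dlimb_t)g[1] << 32) : 0);
      dlimb_t rem;
      r.mag = divmod_u64(a.mag, d, rem);
    } else {
      std::vector<limb_t> rem;
      r.mag = divmod_mag(a.mag, g, rem);
    }
    if (r.mag.empty()) r.sign = 0;
    return r;
  }

  std::string str() const {
    if (sign == 0) return "0";
    std::vector<limb_t> m = mag;
    std::string out;
    while (!m.empty()) {
      dlimb_t rem;
      m = divmod_u64(m, 1000000000ull, rem);
      char buf[16];
      if (m.empty()) snprintf(buf, sizeof buf, "%llu", (unsigned long long)rem);
      else snprintf(buf, sizeof buf, "%09llu", (unsigned long long)rem);
      out = std::string(buf) + out;
    }
    return (sign < 0 ? "-" : "") + out;
  }

  static BigInt from_str(const std::string &s) {
    BigInt r;
    size_t i = 0;
    int sg = 1;
    if (i < s.size() && (s[i] == '-' || s[i] == '+')) { if (s[i] == '-') sg = -1; ++i; }
    if (i >= s.size()) throw std::runtime_error("empty integer literal");
    for (; i < s.size(); ++i) {
      if (s[i] < '0' || s[i] > '9')
        throw std::runtime_error("bad integer literal: " + s);
      // r = r*10 + digit
      dlimb_t carry = (dlimb_t)(s[i] - '0');
      for (size_t k = 0; k < r.mag.size(); ++k) {
        dlimb_t cur = (dlimb_t)r.mag[k] * 10 + carry;
        r.mag[k] = (limb_t)cur;
        carry = cur >> 32;
      }
      if (carry) r.mag.push_back((limb_t)carry);
    }
    trim(r.mag);
    r.sign = r.mag.empty() ? 0 : sg;
    return r;
  }

  // only valid when the value fits; used for exponents / indices
  long long to_ll() const {
    if (mag.size() > 2) throw std::runtime_error("integer too large for index use");
    unsigned long long u = mag.empty() ? 0 : mag[0];
    if (mag.size() == 2) u |= ((unsigned long long)mag[1] << 32);
    return sign < 0 ? -(long long)u : (long long)u;
  }

  // true iff |*this| is a power of two; k receives the exponent
  bool pow2_exponent(long long &k) const {
    if (sign == 0) return false;
    int nz = 0;
    for (size_t i = 0; i < mag.size(); ++i) {
      limb_t v = mag[i];
      if (v) {
        if (v & (v - 1)) return false;
        if (++nz > 1) return false;
        limb_t b = 0; while (!((v >> b) & 1u)) ++b;
        k = 32 * (long long)i + b;
      }
    }
    return nz == 1;
  }
};

struct Rat {
  BigInt num;
  BigInt den;                  // always positive

  Rat() : num(0), den(1) {}
  Rat(long long v) : num(v), den(1) {}
  Rat(const BigInt &n, const BigInt &d) : num(n), den(d) { normalize(); }

  void normalize() {
    if (den.sign == 0) throw std::runtime_error("zero denominator");
    if (den.sign < 0) { den.sign = 1; num.sign = -num.sign; }
    if (num.sign == 0) { den = BigInt(1); return; }
    if (!den.is_one()) {
      std::vector<limb_t> g = gcd_mag(num.mag, den.mag);
      if (!(g.size() == 1 && g[0] == 1)) {
        num = BigInt::div_exact(num, g);
        den = BigInt::div_exact(den, g);
      }
    }
  }

  bool is_zero() const { return num.sign == 0; }
  bool is_integer() const { return den.is_one(); }

  static Rat add(const Rat &a, const Rat &b) {
    Rat r;
    r.num = BigInt::add(BigInt::mul(a.num, b.den), BigInt::mul(b.num, a.den));
    r.den = BigInt::mul(a.den, b.den);
    r.normalize();
    return r;
  }
  static Rat sub(const Rat &a, const Rat &b) { return add(a, b.neg()); }
  static Rat mul(const Rat &a, const Rat &b) {
    Rat r;
    r.num = BigInt::mul(a.num, b.num);
    r.den = BigInt::mul(a.den, b.den);
    r.normalize();
    return r;
  }
  static Rat div(const Rat &a, const Rat &b) {
    if (b.is_zero()) throw std::runtime_error("division by zero");
    Rat r;
    r.num = BigInt::mul(a.num, b.den);
    r.den = BigInt::mul(a.den, b.num);
    r.normalize();
    return r;
  }
  Rat neg() const { Rat r = *this; r.num.sign = -r.num.sign; return r; }
  Rat inv() const {
    if (is_zero()) throw std::runtime_error("division by zero");
    Rat r; r.num = den; r.den = num; r.normalize(); return r;
  }

  static int cmp(const Rat &a, const Rat &b) {
    return BigInt::cmp(BigInt::mul(a.num, b.den), BigInt::mul(b.num, a.den));
  }
  bool operator==(const Rat &o) const {
    return num == o.num && BigInt::cmp(den, o.den) == 0;
  }

  // x^k for integer k (negative allowed); 0^0 = 1 by the package convention
  static Rat pow(const Rat &x, long long k) {
    if (k == 0) return Rat(1);
    if (k < 0) return pow(x.inv(), -k);
    Rat base = x, r(1);
    while (k) {
      if (k & 1) r = mul(r, base);
      base = mul(base, base);
      k >>= 1;
    }
    return r;
  }

  // true iff positive and an exact power of two; k receives log2
  bool pow2_exponent(long long &k) const {
    if (num.sign <= 0) return false;
    long long kn, kd;
    if (den.is_one()) { kd = 0; } else if (den.pow2_exponent(kd)) { } else return false;
    if (num.is_one()) { kn = 0; } else if (num.pow2_exponent(kn)) { } else return false;
    // reduced form: one of num, den is 1 when both are powers of two
    k = kn - kd;
    return true;
  }

  std::string str() const {
    if (den.is_one()) return num.str();
    return num.str() + "/" + den.str();
  }

  static Rat from_str(const std::string &s) {
    size_t slash = s.find('/');
    if (slash == std::string::npos)
      return Rat(BigInt::from_str(s), BigInt(1));
    return Rat(BigInt::from_str(s.substr(0, slash)),
               BigInt::from_str(s.substr(slash + 1)));
  }
};

} // namespace hr

#endif
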
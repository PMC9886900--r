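// BFV homomorphic-encryption engine: RNS ciphertexts over a chain of
// 31-bit NTT-friendly primes, slot batching under a prime plaintext
// modulus, Galois rotations with RNS-decomposed key switching.
//
// Only the operations the packed matrix-multiplication circuit needs are
// implemented: encrypt, decrypt, ct+ct, ct*pt, pt-add, slot rotations.
// There is no ct*ct multiplication, hence no relinearization keys.
//
// Conventions:
//  * ciphertext polynomials are kept in the NTT (evaluation) domain, where
//    Galois automorphisms act as pure slot permutations;
//  * the secret key is ternary, errors are centered-binomial (sigma ~ 3.2);
//  * randomness comes from splitmix64 seeded from R, so a context is
//    reproducible from its seed.  This is a research artifact, not a
//    hardened cryptographic library: the PRNG is not a CSPRNG.

#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <cmath>
#include <vector>
#include <map>

using namespace Rcpp;
typedef uint64_t u64;
typedef unsigned __int128 u128;

// ---------------------------------------------------------------- modular

static inline u64 addmod(u64 a, u64 b, u64 p) { u64 r = a + b; return r >= p ? r - p : r; }
static inline u64 submod(u64 a, u64 b, u64 p) { return a >= b ? a - b : a + p - b; }
// operands < 2^31 so the product fits u64
static inline u64 mulmod31(u64 a, u64 b, u64 p) { return (a * b) % p; }
static inline u64 mulmod128(u64 a, u64 b, u64 p) { return (u64)((u128)a * b % p); }

static u64 powmod(u64 b, u64 e, u64 p) {
  u64 r = 1; b %= p;
  while (e) { if (e & 1) r = mulmod128(r, b, p); b = mulmod128(b, b, p); e >>= 1; }
  return r;
}

static bool is_prime_u64(u64 n) {
  if (n < 2) return false;
  for (u64 d : {2ULL, 3ULL, 5ULL, 7ULL, 11ULL, 13ULL, 17ULL, 19ULL, 23ULL, 29ULL, 31ULL, 37ULL}) {
    if (n % d == 0) return n == d;
  }
  u64 d = n - 1; int s = 0;
  while (!(d & 1)) { d >>= 1; ++s; }
  for (u64 a : {2ULL, 3ULL, 5ULL, 7ULL, 11ULL, 13ULL, 17ULL, 19ULL, 23ULL, 29ULL, 31ULL, 37ULL}) {
    u64 x = powmod(a, d, n);
    if (x == 1 || x == n - 1) continue;
    bool comp = true;
    for (int i = 1; i < s; ++i) {
      x = mulmod128(x, x, n);
      if (x == n - 1) { comp = false; break; }
    }
    if (comp) return false;
  }
  return true;
}

// Shoup multiplication by a precomputed constant: a*w mod p
static inline u64 mulmod_shoup(u64 a, u64 w, u64 ws, u64 p) {
  u64 q = (u64)(((u128)a * ws) >> 64);
  u64 r = a * w - q * p;
  return r >= p ? r - p : r;
}
static inline u64 shoup_of(u64 w, u64 p) { return (u64)((((u128)w) << 64) / p); }

// ------------------------------------------------------------------ bignum
// fixed-width little-endian 384-bit unsigned integer: enough for q
// (< 2^190) times a 64-bit factor plus accumulation slack.

struct Big {
  u64 d[6];
  Big() { memset(d, 0, sizeof(d)); }
  explicit Big(u64 v) { memset(d, 0, sizeof(d)); d[0] = v; }
};

static void big_sub(Big& a, const Big& b) { // assumes a >= b
  u128 borrow = 0;
  for (int i = 0; i < 6; ++i) {
    u128 t = (u128)a.d[i] - b.d[i] - borrow;
    a.d[i] = (u64)t;
    borrow = (t >> 64) ? 1 : 0;
  }
}
static int big_cmp(const Big& a, const Big& b) {
  for (int i = 5; i >= 0; --i)
    if (a.d[i] != b.d[i]) return a.d[i] > b.d[i] ? 1 : -1;
  return 0;
}
static Big big_mul_u64(const Big& a, u64 v) {
  Big r; u128 c = 0;
  for (int i = 0; i < 6; ++i) { c += (u128)a.d[i] * v; r.d[i] = (u64)c; c >>= 64; }
  return r;
}
static void big_addmul_u64(Big& a, const Big& b, u64 v) {
  u128 c = 0;
  for (int i = 0; i < 6; ++i) { c += (u128)a.d[i] + (u128)b.d[i] * v; a.d[i] = (u64)c; c >>= 64; }
}
static Big big_div_u64(const Big& a, u64 v, u64* rem = nullptr) {
  Big q; u128 r = 0;
  for (int i = 5; i >= 0; --i) {
    r = (r << 64) | a.d[i];
    q.d[i] = (u64)(r / v);
    r %= v;
  }
  if (rem) *rem = (u64)r;
  return q;
}
static u64 big_mod_u64(const Big& a, u64 v) {
  u128 r = 0;
  for (int i = 5; i >= 0; --i) r = ((r << 64) | a.d[i]) % v;
  return (u64)r;
}
static long double big_ld(const Big& a) {
  long double r = 0;
  for (int i = 5; i >= 0; --i) r = r * 18446744073709551616.0L + (long double)a.d[i];
  return r;
}
static bool big_is_zero(const Big& a) {
  for (int i = 0; i < 6; ++i) if (a.d[i]) return false;
  return true;
}
static double big_log2(const Big& a) {
  if (big_is_zero(a)) return 0.0;
  return (double)log2l(big_ld(a));
}
// floor(a / m), quotient must fit u64; remainder out
static u64 big_div_big(const Big& a, const Big& m, Big* rem) {
  long double est = big_ld(a) / big_ld(m);
  u64 q = est < 1.0L ? 0 : (u64)est;
  Big prod = big_mul_u64(m, q);
  while (big_cmp(prod, a) > 0) { --q; prod = big_mul_u64(m, q); }
  Big r = a; big_sub(r, prod);
  while (big_cmp(r, m) >= 0) { ++q; big_sub(r, m); }
  if (rem) *rem = r;
  return q;
}

// -------------------------------------------------------------------- prng

struct Prng {
  u64 s;
  explicit Prng(u64 seed) : s(seed) {}
  u64 next() {
    u64 z = (s += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  u64 uniform(u64 p) { return next() % p; }
  int ternary() { return (int)(next() % 3) - 1; }
  // centered binomial, eta = 21: variance 10.5, sigma ~ 3.24
  int cbd() {
    int x = __builtin_popcountll(next() & ((1ULL << 21) - 1));
    int y = __builtin_popcountll(next() & ((1ULL << 21) - 1));
    return x - y;
  }
};

// --------------------------------------------------------------------- NTT

struct NttTab {
  u64 p;
  int n, logn;
  std::vector<u64> wpow, wpow_s;    // omega^k (cyclic root), Shoup companions
  std::vector<u64> wipow, wipow_s;  // omega^{-k}
  std::vector<u64> psi, psi_s;      // zeta^k forward twist
  std::vector<u64> ipsin, ipsin_s;  // zeta^{-k} * n^{-1} combined inverse twist
  std::vector<int> rev;
};

static void ntt_tab_init(NttTab& t, u64 p, int n) {
  t.p = p; t.n = n;
  t.logn = 0; while ((1 << t.logn) < n) ++t.logn;
  u64 m = 2ULL * n;
  if ((p - 1) % m != 0) stop("modulus %s is not NTT-friendly for degree %d",
                             std::to_string(p).c_str(), n);
  u64 zeta = 0;
  for (u64 cand = 2; cand < 100000; ++cand) {
    u64 g = powmod(cand, (p - 1) / m, p);
    if (powmod(g, (u64)n, p) == p - 1) { zeta = g; break; }
  }
  if (!zeta) stop("no primitive 2n-th root of unity found");
  u64 omega = mulmod128(zeta, zeta, p);
  u64 iomega = powmod(omega, p - 2, p);
  u64 izeta = powmod(zeta, p - 2, p);
  u64 ninv = powmod((u64)n, p - 2, p);
  t.wpow.resize(n); t.wipow.resize(n); t.psi.resize(n); t.ipsin.resize(n);
  u64 w = 1, wi = 1, ps = 1, ips = ninv;
  for (int k = 0; k < n; ++k) {
    t.wpow[k] = w; t.wipow[k] = wi; t.psi[k] = ps; t.ipsin[k] = ips;
    w = mulmod128(w, omega, p); wi = mulmod128(wi, iomega, p);
    ps = mulmod128(ps, zeta, p); ips = mulmod128(ips, izeta, p);
  }
  t.wpow_s.resize(n); t.wipow_s.resize(n); t.psi_s.resize(n); t.ipsin_s.resize(n);
  for (int k = 0; k < n; ++k) {
    t.wpow_s[k] = shoup_of(t.wpow[k], p);
    t.wipow_s[k] = shoup_of(t.wipow[k], p);
    t.psi_s[k] = shoup_of(t.psi[k], p);
    t.ipsin_s[k] = shoup_of(t.ipsin[k], p);
  }
  t.rev.resize(n);
  for (int i = 0; i < n; ++i) {
    int r = 0;
    for (int b = 0; b < t.logn; ++b) if (i & (1 << b)) r |= 1 << (t.logn - 1 - b);
    t.rev[i] = r;
  }
}

// Shoup product without the final correction: result in [0, 2p) for any a
static inline u64 mulmod_shoup_lazy(u64 a, u64 w, u64 ws, u64 p) {
  u64 q = (u64)(((u128)a * ws) >> 64);
  return a * w - q * p;
}

// cyclic DFT: A[i] = sum_k a[k] w^{ik}; natural order in and out.
// Lazy Harvey butterflies: intermediate values live in [0, 4p) (p < 2^31),
// callers reduce on the way out.
static void dft(std::vector<u64>& a, const NttTab& t, bool inverse) {
  const int n = t.n;
  const u64 p = t.p, twop = 2 * t.p;
  const std::vector<u64>& W = inverse ? t.wipow : t.wpow;
  const std::vector<u64>& Ws = inverse ? t.wipow_s : t.wpow_s;
  for (int i = 0; i < n; ++i) if (i < t.rev[i]) std::swap(a[i], a[t.rev[i]]);
  for (int len = 2; len <= n; len <<= 1) {
    int stride = n / len, half = len >> 1;
    for (int i = 0; i < n; i += len) {
      int widx = 0;
      u64* lo = a.data() + i;
      u64* hi = lo + half;
      for (int j = 0; j < half; ++j) {
        u64 u = lo[j];
        if (u >= twop) u -= twop;
        u64 v = mulmod_shoup_lazy(hi[j], W[widx], Ws[widx], p);
        lo[j] = u + v;
        hi[j] = u + twop - v;
        widx += stride;
      }
    }
  }
}

// negacyclic forward transform: A[i] = a(zeta^{2i+1}), fully reduced output
static void ntt_fwd(std::vector<u64>& a, const NttTab& t) {
  const u64 p = t.p, twop = 2 * t.p;
  for (int k = 0; k < t.n; ++k) a[k] = mulmod_shoup(a[k], t.psi[k], t.psi_s[k], p);
  dft(a, t, false);
  for (int k = 0; k < t.n; ++k) {
    u64 v = a[k];
    if (v >= twop) v -= twop;
    if (v >= p) v -= p;
    a[k] = v;
  }
}
static void ntt_inv(std::vector<u64>& a, const NttTab& t) {
  dft(a, t, true);
  const u64 p = t.p;
  for (int k = 0; k < t.n; ++k) {
    u64 v = mulmod_shoup_lazy(a[k], t.ipsin[k], t.ipsin_s[k], p);
    a[k] = v >= p ? v - p : v;
  }
}

// ----------------------------------------------------------------- context

// homomorphic-encryption standard: maximum log2(q) at 128-bit classical
static int max_logq_128(int n) {
  switch (n) {
    case 8192: return 218;
    case 16384: return 438;
    case 32768: return 881;
    default: return 0;
  }
}

static const int NPRIMES = 6;

struct GaloisKey {
  // ksk[i][c]: decomposition index i over RNS primes, component c in {0,1};
  // each entry holds k polys of n words, NTT domain, prime-major
  std::vector<std::vector<std::vector<u64>>> ksk;
};

struct Ctx {
  int n, logn, k;
  std::vector<u64> qp;
  std::vector<NttTab> qt;
  u64 T[2];
  NttTab tt[2];
  std::vector<int> imap;                    // slot j -> evaluation index
  Big q, half_q;
  std::vector<Big> qtilde;                  // (q/p_i) ((q/p_i)^{-1} mod p_i)
  std::vector<std::vector<u64>> qtilde_mod; // qtilde[i] mod p_j
  Big delta[2];                             // floor(q / t)
  std::vector<u64> delta_mod[2];
  bool has_sk;
  std::vector<std::vector<u64>> sk, pk0, pk1;  // per prime, NTT domain
  std::map<u64, GaloisKey> gk;
  std::map<u64, std::vector<int>> gperm;
  std::vector<u64> pow3;                    // 3^j mod 2n
  Prng rng;
  Ctx() : rng(0) {}
};

static std::vector<u64> pick_primes(int n, int count) {
  std::vector<u64> out;
  u64 m = 2ULL * n;
  // largest p < 2^31 with p = 1 mod 2n, walking down
  u64 p = ((((1ULL << 31) - 2) / m) * m) + 1;
  while ((int)out.size() < count && p > (1ULL << 30)) {
    if (is_prime_u64(p)) out.push_back(p);
    p -= m;
  }
  if ((int)out.size() < count) stop("could not find enough RNS primes");
  return out;
}

static void perm_for_galois(const Ctx& c, u64 g, std::vector<int>& perm) {
  u64 m = 2ULL * c.n;
  perm.resize(c.n);
  for (int i = 0; i < c.n; ++i) {
    u64 e = ((2ULL * i + 1) * g) % m;       // odd, so (e-1)/2 is integral
    perm[i] = (int)((e - 1) / 2);
  }
}

// sample a small signed polynomial and spread it over all RNS primes in
// the NTT domain
static void small_poly_ntt(Ctx& c, bool ternary,
                           std::vector<std::vector<u64>>& out) {
  std::vector<int> e(c.n);
  for (int i = 0; i < c.n; ++i) e[i] = ternary ? c.rng.ternary() : c.rng.cbd();
  out.assign(c.k, std::vector<u64>(c.n));
  for (int j = 0; j < c.k; ++j) {
    u64 p = c.qp[j];
    for (int i = 0; i < c.n; ++i)
      out[j][i] = e[i] >= 0 ? (u64)e[i] : p - (u64)(-e[i]);
    ntt_fwd(out[j], c.qt[j]);
  }
}

static void make_galois_key(Ctx& c, u64 g) {
  std::vector<int> perm;
  perm_for_galois(c, g, perm);
  c.gperm[g] = perm;
  GaloisKey key;
  key.ksk.assign(c.k, std::vector<std::vector<u64>>(2));
  for (int i = 0; i < c.k; ++i) {
    // a_i uniform in NTT domain; e_i small
    std::vector<std::vector<u64>> a(c.k, std::vector<u64>(c.n));
    for (int j = 0; j < c.k; ++j)
      for (int s = 0; s < c.n; ++s) a[j][s] = c.rng.uniform(c.qp[j]);
    std::vector<std::vector<u64>> e;
    small_poly_ntt(c, false, e);
    std::vector<u64> k0(c.k * (size_t)c.n), k1(c.k * (size_t)c.n);
    for (int j = 0; j < c.k; ++j) {
      u64 p = c.qp[j];
      u64 qt = c.qtilde_mod[i][j];
      for (int s = 0; s < c.n; ++s) {
        u64 skg = c.sk[j][perm[s]];                    // phi_g(sk) in NTT domain
        u64 v = mulmod31(qt, skg, p);
        v = submod(v, mulmod31(a[j][s], c.sk[j][s], p), p);
        v = submod(v, e[j][s], p);
        k0[(size_t)j * c.n + s] = v;
        k1[(size_t)j * c.n + s] = a[j][s];
      }
    }
    key.ksk[i][0] = std::move(k0);
    key.ksk[i][1] = std::move(k1);
  }
  c.gk[g] = std::move(key);
}

static void ctx_tables(Ctx& c, int n, u64 t0, u64 t1) {
  if (n < 2 || (n & (n - 1)) != 0) stop("polynomial degree must be a power of two");
  if (max_logq_128(n) == 0)
    stop("polynomial degree %d cannot reach 128-bit security with this modulus chain", n);
  c.n = n;
  c.logn = 0; while ((1 << c.logn) < n) ++c.logn;
  c.T[0] = t0; c.T[1] = t1;
  for (int ti = 0; ti < 2; ++ti) {
    u64 t = c.T[ti];
    if (t >= (1ULL << 31)) stop("plaintext modulus must be below 2^31");
    if (!is_prime_u64(t)) stop("plaintext modulus %s is not prime", std::to_string(t).c_str());
    if ((t - 1) % (2ULL * n) != 0)
      stop("plaintext modulus %s does not support batching at degree %d",
           std::to_string(t).c_str(), n);
  }
  c.k = NPRIMES;
  c.qp = pick_primes(n, c.k);
  double logq = 0;
  for (u64 p : c.qp) logq += std::log2((double)p);
  if (logq > max_logq_128(n))
    stop("ciphertext modulus too large for 128-bit security at degree %d", n);
  c.qt.resize(c.k);
  for (int j = 0; j < c.k; ++j) ntt_tab_init(c.qt[j], c.qp[j], n);
  ntt_tab_init(c.tt[0], t0, n);
  ntt_tab_init(c.tt[1], t1, n);
  // batching index map: slot j (first half) sits at exponent 3^j mod 2n,
  // slot j + n/2 at exponent -3^j
  u64 m = 2ULL * n;
  c.pow3.resize(n);
  u64 pw = 1;
  for (int j = 0; j < n; ++j) { c.pow3[j] = pw; pw = (pw * 3) % m; }
  c.imap.resize(n);
  for (int j = 0; j < n / 2; ++j) {
    c.imap[j] = (int)((c.pow3[j] - 1) / 2);
    c.imap[j + n / 2] = (int)((m - c.pow3[j] - 1) / 2);
  }
  // CRT constants
  c.q = Big(1);
  for (u64 p : c.qp) c.q = big_mul_u64(c.q, p);
  c.half_q = big_div_u64(c.q, 2);
  c.qtilde.resize(c.k);
  c.qtilde_mod.assign(c.k, std::vector<u64>(c.k));
  for (int i = 0; i < c.k; ++i) {
    Big qi = big_div_u64(c.q, c.qp[i]);
    u64 r = big_mod_u64(qi, c.qp[i]);
    u64 inv = powmod(r, c.qp[i] - 2, c.qp[i]);
    c.qtilde[i] = big_mul_u64(qi, inv);
    for (int j = 0; j < c.k; ++j)
      c.qtilde_mod[i][j] = big_mod_u64(c.qtilde[i], c.qp[j]);
  }
  for (int ti = 0; ti < 2; ++ti) {
    c.delta[ti] = big_div_u64(c.q, c.T[ti]);
    c.delta_mod[ti].resize(c.k);
    for (int j = 0; j < c.k; ++j)
      c.delta_mod[ti][j] = big_mod_u64(c.delta[ti], c.qp[j]);
  }
}

static void ctx_keygen(Ctx& c, u64 seed) {
  c.rng = Prng(seed);
  c.has_sk = true;
  small_poly_ntt(c, true, c.sk);
  // pk1 = a uniform, pk0 = -(a*s + e)
  c.pk0.assign(c.k, std::vector<u64>(c.n));
  c.pk1.assign(c.k, std::vector<u64>(c.n));
  std::vector<std::vector<u64>> e;
  small_poly_ntt(c, false, e);
  for (int j = 0; j < c.k; ++j) {
    u64 p = c.qp[j];
    for (int s = 0; s < c.n; ++s) {
      c.pk1[j][s] = c.rng.uniform(p);
      u64 v = addmod(mulmod31(c.pk1[j][s], c.sk[j][s], p), e[j][s], p);
      c.pk0[j][s] = v == 0 ? 0 : p - v;
    }
  }
  // rotation keys for the power-of-two ladder plus the half-swap
  for (int r = 1; r <= c.n / 4; r <<= 1) make_galois_key(c, c.pow3[r]);
  make_galois_key(c, 2ULL * c.n - 1);
}

// -------------------------------------------------------- raw (de)serialize

static const u64 MAGIC_CT = 0x42465643540001ULL;
static const u64 MAGIC_PT = 0x42465650540001ULL;

typedef std::vector<std::vector<u64>> PolyRns;  // [prime][coeff]

struct CtView {
  int n, k, npoly;
  std::vector<PolyRns> poly;
};

static RawVector pack_ct(const Ctx& c, const std::vector<PolyRns>& polys, u64 magic) {
  size_t words = 4 + polys.size() * (size_t)c.k * c.n;
  RawVector out(words * 8);
  u64* w = (u64*)RAW(out);
  w[0] = magic; w[1] = (u64)c.n; w[2] = (u64)c.k; w[3] = (u64)polys.size();
  size_t off = 4;
  for (const PolyRns& pl : polys)
    for (int j = 0; j < c.k; ++j) {
      memcpy(w + off, pl[j].data(), (size_t)c.n * 8);
      off += c.n;
    }
  return out;
}

static CtView unpack_ct(const Ctx& c, const RawVector& r, u64 magic) {
  if ((size_t)r.size() < 32) stop("truncated ciphertext");
  const u64* w = (const u64*)RAW(r);
  if (w[0] != magic) stop("wrong payload type (bad magic)");
  CtView v;
  v.n = (int)w[1]; v.k = (int)w[2]; v.npoly = (int)w[3];
  if (v.n != c.n || v.k != c.k) stop("ciphertext does not match this context");
  size_t need = (4 + (size_t)v.npoly * v.k * v.n) * 8;
  if ((size_t)r.size() != need) stop("truncated ciphertext");
  size_t off = 4;
  v.poly.resize(v.npoly);
  for (int pI = 0; pI < v.npoly; ++pI) {
    v.poly[pI].assign(v.k, std::vector<u64>(v.n));
    for (int j = 0; j < v.k; ++j) {
      memcpy(v.poly[pI][j].data(), w + off, (size_t)v.n * 8);
      off += v.n;
    }
  }
  return v;
}

// -------------------------------------------------------------- encode ops

// slot vector -> plaintext coefficients mod t
static std::vector<u64> slots_to_coeffs(const Ctx& c, const NumericVector& slots, int ti) {
  u64 t = c.T[ti];
  if (slots.size() > c.n) stop("more slot values than slots");
  std::vector<u64> ev(c.n, 0);
  for (int j = 0; j < slots.size(); ++j) {
    double v = slots[j];
    if (!(v >= 0) || v >= (double)t || v != std::floor(v))
      stop("slot value at position %d is not an integer in [0, t)", j + 1);
    ev[c.imap[j]] = (u64)v;
  }
  ntt_inv(ev, c.tt[ti]);
  return ev;
}

static NumericVector coeffs_to_slots(const Ctx& c, std::vector<u64> m, int ti) {
  ntt_fwd(m, c.tt[ti]);
  NumericVector out(c.n);
  for (int j = 0; j < c.n; ++j) out[j] = (double)m[c.imap[j]];
  return out;
}

// ------------------------------------------------------------- public API

// [[Rcpp::export(name = ".bfv_ctx_new")]]
SEXP bfv_ctx_new(int n, double t0, double t1, double seed) {
  Ctx* c = new Ctx();
  ctx_tables(*c, n, (u64)t0, (u64)t1);
  ctx_keygen(*c, (u64)seed);
  XPtr<Ctx> p(c, true);
  return p;
}

// [[Rcpp::export(name = ".bfv_ctx_info")]]
List bfv_ctx_info(SEXP ctx) {
  XPtr<Ctx> c(ctx);
  NumericVector primes(c->k);
  double logq = 0;
  for (int j = 0; j < c->k; ++j) { primes[j] = (double)c->qp[j]; logq += std::log2((double)c->qp[j]); }
  return List::create(
    _["n"] = c->n, _["k"] = c->k, _["primes"] = primes,
    _["log_q"] = logq, _["max_log_q_128"] = max_logq_128(c->n),
    _["t0"] = (double)c->T[0], _["t1"] = (double)c->T[1],
    _["has_secret_key"] = c->has_sk,
    _["n_galois_keys"] = (int)c->gk.size());
}

// [[Rcpp::export(name = ".bfv_encrypt")]]
RawVector bfv_encrypt(SEXP ctx, NumericVector slots, int ti) {
  XPtr<Ctx> c(ctx);
  if (ti < 0 || ti > 1) stop("ti must be 0 or 1");
  std::vector<u64> m = slots_to_coeffs(*c, slots, ti);
  std::vector<int> u(c->n), e1(c->n), e2(c->n);
  for (int i = 0; i < c->n; ++i) u[i] = c->rng.ternary();
  for (int i = 0; i < c->n; ++i) e1[i] = c->rng.cbd();
  for (int i = 0; i < c->n; ++i) e2[i] = c->rng.cbd();
  std::vector<PolyRns> out(2, PolyRns(c->k));
  for (int j = 0; j < c->k; ++j) {
    u64 p = c->qp[j];
    std::vector<u64> un(c->n), w(c->n), v2(c->n);
    for (int i = 0; i < c->n; ++i) {
      un[i] = u[i] >= 0 ? (u64)u[i] : p - 1;
      u64 dm = mulmod31(c->delta_mod[ti][j], m[i] % p, p);
      u64 ee = e1[i] >= 0 ? (u64)e1[i] : p - (u64)(-e1[i]);
      w[i] = addmod(dm, ee, p);
      v2[i] = e2[i] >= 0 ? (u64)e2[i] : p - (u64)(-e2[i]);
    }
    ntt_fwd(un, c->qt[j]);
    ntt_fwd(w, c->qt[j]);
    ntt_fwd(v2, c->qt[j]);
    out[0][j].resize(c->n);
    out[1][j].resize(c->n);
    for (int i = 0; i < c->n; ++i) {
      out[0][j][i] = addmod(mulmod31(c->pk0[j][i], un[i], p), w[i], p);
      out[1][j][i] = addmod(mulmod31(c->pk1[j][i], un[i], p), v2[i], p);
    }
  }
  return pack_ct(*c, out, MAGIC_CT);
}

// decrypt to slot values in [0, t); attribute "noise_budget" in bits
// [[Rcpp::export(name = ".bfv_decrypt")]]
NumericVector bfv_decrypt(SEXP ctx, RawVector ct, int ti) {
  XPtr<Ctx> c(ctx);
  if (!c->has_sk) stop("this context holds no secret key");
  if (ti < 0 || ti > 1) stop("ti must be 0 or 1");
  CtView v = unpack_ct(*c, ct, MAGIC_CT);
  if (v.npoly != 2) stop("malformed ciphertext");
  u64 t = c->T[ti];
  std::vector<std::vector<u64>> coeff(c->k);
  for (int j = 0; j < c->k; ++j) {
    u64 p = c->qp[j];
    std::vector<u64> acc(c->n);
    for (int i = 0; i < c->n; ++i)
      acc[i] = addmod(v.poly[0][j][i], mulmod31(v.poly[1][j][i], c->sk[j][i], p), p);
    ntt_inv(acc, c->qt[j]);
    coeff[j] = std::move(acc);
  }
  std::vector<u64> m(c->n);
  Big maxr;
  for (int i = 0; i < c->n; ++i) {
    Big S;
    for (int j = 0; j < c->k; ++j) big_addmul_u64(S, c->qtilde[j], coeff[j][i]);
    Big V;
    big_div_big(S, c->q, &V);                 // V = S mod q
    Big Q = big_mul_u64(V, t);
    Big r;
    u64 u = big_div_big(Q, c->q, &r);
    Big twice = big_mul_u64(r, 2);
    if (big_cmp(twice, c->q) >= 0) {          // round up; distance is q - r
      ++u;
      Big d = c->q; big_sub(d, r); r = d;
    }
    m[i] = u % t;
    if (big_cmp(r, maxr) > 0) maxr = r;
  }
  double budget = big_log2(c->q) - 1.0 - big_log2(maxr);
  if (budget < 0) budget = 0;
  NumericVector out = coeffs_to_slots(*c, m, ti);
  out.attr("noise_budget") = budget;
  return out;
}

// encode a slot vector as an NTT-domain multiplication operand.
// Residues above t/2 are centre-lifted to negative representatives to keep
// the noise growth of ct*pt multiplication at ||pt||-scale.
// [[Rcpp::export(name = ".bfv_encode_plain")]]
RawVector bfv_encode_plain(SEXP ctx, NumericVector slots, int ti) {
  XPtr<Ctx> c(ctx);
  if (ti < 0 || ti > 1) stop("ti must be 0 or 1");
  std::vector<u64> m = slots_to_coeffs(*c, slots, ti);
  u64 t = c->T[ti];
  std::vector<PolyRns> out(1, PolyRns(c->k));
  for (int j = 0; j < c->k; ++j) {
    u64 p = c->qp[j];
    out[0][j].resize(c->n);
    for (int i = 0; i < c->n; ++i) {
      u64 mi = m[i];
      out[0][j][i] = mi > t / 2 ? p - ((t - mi) % p) : mi % p;
      if (out[0][j][i] == p) out[0][j][i] = 0;
    }
    ntt_fwd(out[0][j], c->qt[j]);
  }
  return pack_ct(*c, out, MAGIC_PT);
}

// [[Rcpp::export(name = ".bfv_mul_plain")]]
RawVector bfv_mul_plain(SEXP ctx, RawVector ct, RawVector pt) {
  XPtr<Ctx> c(ctx);
  CtView v = unpack_ct(*c, ct, MAGIC_CT);
  CtView w = unpack_ct(*c, pt, MAGIC_PT);
  if (v.npoly != 2 || w.npoly != 1) stop("malformed operands");
  for (int pI = 0; pI < 2; ++pI)
    for (int j = 0; j < c->k; ++j) {
      u64 p = c->qp[j];
      for (int i = 0; i < c->n; ++i)
        v.poly[pI][j][i] = mulmod31(v.poly[pI][j][i], w.poly[0][j][i], p);
    }
  return pack_ct(*c, v.poly, MAGIC_CT);
}

// [[Rcpp::export(name = ".bfv_add_ct")]]
RawVector bfv_add_ct(SEXP ctx, RawVector a, RawVector b) {
  XPtr<Ctx> c(ctx);
  CtView x = unpack_ct(*c, a, MAGIC_CT);
  CtView y = unpack_ct(*c, b, MAGIC_CT);
  if (x.npoly != 2 || y.npoly != 2) stop("malformed ciphertexts");
  for (int pI = 0; pI < 2; ++pI)
    for (int j = 0; j < c->k; ++j) {
      u64 p = c->qp[j];
      for (int i = 0; i < c->n; ++i)
        x.poly[pI][j][i] = addmod(x.poly[pI][j][i], y.poly[pI][j][i], p);
    }
  return pack_ct(*c, x.poly, MAGIC_CT);
}

// add an (unencrypted) slot vector: c0 += Delta * encode(slots)
// [[Rcpp::export(name = ".bfv_add_plain")]]
RawVector bfv_add_plain(SEXP ctx, RawVector ct, NumericVector slots, int ti) {
  XPtr<Ctx> c(ctx);
  if (ti < 0 || ti > 1) stop("ti must be 0 or 1");
  CtView v = unpack_ct(*c, ct, MAGIC_CT);
  if (v.npoly != 2) stop("malformed ciphertext");
  std::vector<u64> m = slots_to_coeffs(*c, slots, ti);
  for (int j = 0; j < c->k; ++j) {
    u64 p = c->qp[j];
    std::vector<u64> dm(c->n);
    for (int i = 0; i < c->n; ++i)
      dm[i] = mulmod31(c->delta_mod[ti][j], m[i] % p, p);
    ntt_fwd(dm, c->qt[j]);
    for (int i = 0; i < c->n; ++i)
      v.poly[0][j][i] = addmod(v.poly[0][j][i], dm[i], p);
  }
  return pack_ct(*c, v.poly, MAGIC_CT);
}

static RawVector apply_galois(Ctx& c, const RawVector& ct, u64 g) {
  auto itK = c.gk.find(g);
  if (itK == c.gk.end()) stop("no Galois key for this rotation");
  const std::vector<int>& perm = c.gperm[g];
  CtView v = unpack_ct(c, ct, MAGIC_CT);
  if (v.npoly != 2) stop("malformed ciphertext");
  // 1. permute both components (automorphism in the NTT domain)
  std::vector<PolyRns> pc(2, PolyRns(c.k, std::vector<u64>(c.n)));
  for (int pI = 0; pI < 2; ++pI)
    for (int j = 0; j < c.k; ++j)
      for (int i = 0; i < c.n; ++i)
        pc[pI][j][i] = v.poly[pI][j][perm[i]];
  // 2. key-switch the second component back to sk
  std::vector<std::vector<u64>> cf(c.k);
  for (int j = 0; j < c.k; ++j) {
    cf[j] = pc[1][j];
    ntt_inv(cf[j], c.qt[j]);
  }
  // d[i][j]: coefficients of pc[1] mod p_i redistributed to prime j, NTT'd
  std::vector<std::vector<std::vector<u64>>> d(
      c.k, std::vector<std::vector<u64>>(c.k));
  for (int i = 0; i < c.k; ++i)
    for (int j = 0; j < c.k; ++j) {
      u64 p = c.qp[j];
      std::vector<u64> dj(c.n);
      for (int s = 0; s < c.n; ++s) {
        u64 x = cf[i][s];
        dj[s] = x >= p ? x - p : x;
      }
      ntt_fwd(dj, c.qt[j]);
      d[i][j] = std::move(dj);
    }
  std::vector<PolyRns> out(2, PolyRns(c.k, std::vector<u64>(c.n)));
  const GaloisKey& key = itK->second;
  for (int j = 0; j < c.k; ++j) {
    u64 p = c.qp[j];
    for (int s = 0; s < c.n; ++s) {
      u128 acc0 = pc[0][j][s], acc1 = 0;
      for (int i = 0; i < c.k; ++i) {
        u64 ds = d[i][j][s];
        acc0 += (u128)ds * key.ksk[i][0][(size_t)j * c.n + s];
        acc1 += (u128)ds * key.ksk[i][1][(size_t)j * c.n + s];
      }
      out[0][j][s] = (u64)(acc0 % p);
      out[1][j][s] = (u64)(acc1 % p);
    }
  }
  return pack_ct(c, out, MAGIC_CT);
}

// rotate slot rows left by `steps` (a power of two <= n/4)
// [[Rcpp::export(name = ".bfv_rotate_rows")]]
RawVector bfv_rotate_rows(SEXP ctx, RawVector ct, int steps) {
  XPtr<Ctx> c(ctx);
  if (steps < 1 || steps > c->n / 4 || (steps & (steps - 1)) != 0)
    stop("rotation step must be a power of two between 1 and n/4");
  return apply_galois(*c, ct, c->pow3[steps]);
}

// swap the two slot halves
// [[Rcpp::export(name = ".bfv_rotate_cols")]]
RawVector bfv_rotate_cols(SEXP ctx, RawVector ct) {
  XPtr<Ctx> c(ctx);
  return apply_galois(*c, ct, 2ULL * c->n - 1);
}

// [[Rcpp::export(name = ".bfv_noise_budget")]]
double bfv_noise_budget(SEXP ctx, RawVector ct, int ti) {
  NumericVector d = bfv_decrypt(ctx, ct, ti);
  return as<double>(d.attr("noise_budget"));
}

// ------------------------------------------------- public-material export

// serialize everything an evaluator needs (no secret key)
// [[Rcpp::export(name = ".bfv_public_blob")]]
RawVector bfv_public_blob(SEXP ctx) {
  XPtr<Ctx> c(ctx);
  size_t per_poly = (size_t)c->k * c->n;
  size_t nkeys = c->gk.size();
  size_t words = 6 + 2 * per_poly + nkeys * (1 + (size_t)c->k * 2 * per_poly);
  RawVector out(words * 8);
  u64* w = (u64*)RAW(out);
  size_t off = 0;
  w[off++] = 0x42465642ULL;  // blob magic
  w[off++] = (u64)c->n;
  w[off++] = (u64)c->k;
  w[off++] = c->T[0];
  w[off++] = c->T[1];
  w[off++] = (u64)nkeys;
  for (int j = 0; j < c->k; ++j) { memcpy(w + off, c->pk0[j].data(), (size_t)c->n * 8); off += c->n; }
  for (int j = 0; j < c->k; ++j) { memcpy(w + off, c->pk1[j].data(), (size_t)c->n * 8); off += c->n; }
  for (auto& kv : c->gk) {
    w[off++] = kv.first;
    for (int i = 0; i < c->k; ++i)
      for (int comp = 0; comp < 2; ++comp) {
        memcpy(w + off, kv.second.ksk[i][comp].data(), per_poly * 8);
        off += per_poly;
      }
  }
  return out;
}

// [[Rcpp::export(name = ".bfv_ctx_from_blob")]]
SEXP bfv_ctx_from_blob(RawVector blob) {
  if (blob.size() < 48) stop("truncated public blob");
  const u64* w = (const u64*)RAW(blob);
  size_t off = 0;
  if (w[off++] != 0x42465642ULL) stop("not a public-material blob");
  int n = (int)w[off++];
  int k = (int)w[off++];
  u64 t0 = w[off++], t1 = w[off++];
  size_t nkeys = (size_t)w[off++];
  Ctx* c = new Ctx();
  ctx_tables(*c, n, t0, t1);
  if (c->k != k) { delete c; stop("prime count mismatch in blob"); }
  size_t per_poly = (size_t)c->k * c->n;
  size_t need = (6 + 2 * per_poly + nkeys * (1 + (size_t)c->k * 2 * per_poly)) * 8;
  if ((size_t)blob.size() != need) { delete c; stop("truncated public blob"); }
  c->has_sk = false;
  c->rng = Prng(0);
  c->pk0.assign(c->k, std::vector<u64>(c->n));
  c->pk1.assign(c->k, std::vector<u64>(c->n));
  for (int j = 0; j < c->k; ++j) { memcpy(c->pk0[j].data(), w + off, (size_t)c->n * 8); off += c->n; }
  for (int j = 0; j < c->k; ++j) { memcpy(c->pk1[j].data(), w + off, (size_t)c->n * 8); off += c->n; }
  for (size_t kk = 0; kk < nkeys; ++kk) {
    u64 g = w[off++];
    GaloisKey key;
    key.ksk.assign(c->k, std::vector<std::vector<u64>>(2));
    for (int i = 0; i < c->k; ++i)
      for (int comp = 0; comp < 2; ++comp) {
        key.ksk[i][comp].resize(per_poly);
        memcpy(key.ksk[i][comp].data(), w + off, per_poly * 8);
        off += per_poly;
      }
    c->gk[g] = std::move(key);
    std::vector<int> perm;
    perm_for_galois(*c, g, perm);
    c->gperm[g] = perm;
  }
  XPtr<Ctx> p(c, true);
  return p;
}
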
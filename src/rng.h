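#ifndef SMCLOOP_RNG_H
#define SMCLOOP_RNG_H

#include <cstdint>
#include <cmath>

// xoshiro256++ seeded through splitmix64. One generator per logical stream
// (thermal noise / capture selection) so capture decisions are reproducible
// independently of how much dynamics ran before them.
struct Xoshiro {
  uint64_t s[4];

  static uint64_t splitmix(uint64_t &x) {
    x += 0x9E3779B97F4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }

  // seed from (user seed, replicate id, stream id)
  void seed(uint64_t base, uint64_t rep, uint64_t stream) {
    uint64_t x = base * 0x9E3779B97F4A7C15ULL;
    x ^= (rep + 1) * 0xD1B54A32D192ED03ULL;
    x ^= (stream + 1) * 0x94D049BB133111EBULL;
    for (int i = 0; i < 4; ++i) s[i] = splitmix(x);
    if (!(s[0] | s[1] | s[2] | s[3])) s[0] = 0x1ULL;
  }

  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  inline uint32_t next32() { return (uint32_t)(next() >> 32); }

  // uniform in [0, 1)
  inline double unif() { return (double)(next() >> 11) * 0x1.0p-53; }
  // uniform in (0, 1): safe for log()
  inline double unif_open() {
    return ((double)(next() >> 11) + 0.5) * 0x1.0p-53;
  }
  // uniform integer in {0, ..., n-1}, n small
  inline int randint(int n) {
    int k = (int)(unif() * (double)n);
    return k >= n ? n - 1 : k;
  }
};

// Marsaglia-Tsang ziggurat for the standard normal (128 layers).
struct Ziggurat {
  uint32_t kn[128];
  double wn[128], fn[128];

  Ziggurat() {
    const double m1 = 2147483648.0;
    double dn = 3.442619855899, tn = dn;
    const double vn = 9.91256303526217e-3;
    double q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = (uint32_t)((dn / q) * m1);
    kn[1] = 0;
    wn[0] = q / m1;
    wn[127] = dn / m1;
    fn[0] = 1.0;
    fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; --i) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = (uint32_t)((dn / tn) * m1);
      tn = dn;
      fn[i] = std::exp(-0.5 * dn * dn);
      wn[i] = dn / m1;
    }
  }

  inline double draw(Xoshiro &rng) const {
    for (;;) {
      int32_t hz = (int32_t)rng.next32();
      uint32_t iz = (uint32_t)hz & 127u;
      uint32_t ahz = (hz < 0) ? (uint32_t)(-(int64_t)hz) : (uint32_t)hz;
      if (ahz < kn[iz]) return hz * wn[iz];
      const double r = 3.442619855899;
      if (iz == 0) {  // tail
        double x, y;
        do {
          x = -std::log(rng.unif_open()) / r;
          y = -std::log(rng.unif_open());
        } while (y + y < x * x);
        return hz > 0 ? r + x : -r - x;
      }
      double x = hz * wn[iz];
      if (fn[iz] + rng.unif() * (fn[iz - 1] - fn[iz]) <
          std::exp(-0.5 * x * x))
        return x;
    }
  }
};

#endif
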
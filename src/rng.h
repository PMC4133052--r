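// Minimal xoshiro256++ generator for the hot simulation loops, seeded
// deterministically from R's RNG stream (so set.seed() governs every run).
#ifndef VALLEYCROSS_RNG_H
#define VALLEYCROSS_RNG_H

#include <Rcpp.h>
#include <cstdint>
#include <cmath>

struct FastRng {
  uint64_t s[4];

  static uint64_t splitmix64(uint64_t& x) {
    x += 0x9e3779b97f4a7c15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }

  // seed from R's RNG: reproducible under set.seed()
  explicit FastRng() {
    uint64_t seed = (uint64_t)(unif_rand() * 4294967296.0) ^
                    ((uint64_t)(unif_rand() * 4294967296.0) << 32);
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(seed);
  }

  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }

  inline double runif() {            // uniform on (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }

  inline double rexp() {             // standard exponential
    return -std::log(runif());
  }
};

#endif
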
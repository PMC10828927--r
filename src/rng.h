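#ifndef TUMBLETURN_RNG_H
#define TUMBLETURN_RNG_H

#include <cstdint>
#include <cmath>

// Counter-based pseudo-random numbers: every variate is a pure function of
// (seed, stream, particle, counter), so particle streams are independent of
// the number of particles integrated together and a resumed run consumes
// exactly the same variates as one long run.
static inline uint64_t tt_mix(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline uint64_t tt_key(uint64_t seed, uint64_t stream,
                              uint64_t particle, uint64_t counter) {
  return tt_mix(tt_mix(tt_mix(seed ^ 0xD1B54A32D192ED03ULL) + stream) +
                tt_mix(particle * 0x2545F4914F6CDD1DULL + counter));
}

// uniform in (0, 1)
static inline double tt_unif(uint64_t seed, uint64_t stream,
                             uint64_t particle, uint64_t counter) {
  uint64_t k = tt_key(seed, stream, particle, counter);
  return ((k >> 11) + 0.5) * (1.0 / 9007199254740992.0);
}

// standard normal via Box-Muller; one hash per variate (the two uniforms
// come from the high and low 32 bits), stateless in the counter
static inline double tt_norm(uint64_t seed, uint64_t stream,
                             uint64_t particle, uint64_t counter) {
  uint64_t k = tt_key(seed, stream, particle, counter);
  double u1 = ((k >> 32) + 0.5) * (1.0 / 4294967296.0);
  double u2 = ((k & 0xFFFFFFFFULL) + 0.5) * (1.0 / 4294967296.0);
  return std::sqrt(-2.0 * std::log(u1)) * std::cos(6.283185307179586 * u2);
}

#endif
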
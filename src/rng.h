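#ifndef ACTIONDDM_RNG_H
#define ACTIONDDM_RNG_H

#include <cstdint>
#include <cmath>
#include <random>

// Deterministic RNG across platforms: mt19937_64 output is fully specified by
// the C++ standard; std::normal_distribution is not, so normals come from our
// own Box-Muller transform.
struct Rng {
  std::mt19937_64 g;
  bool have_spare;
  double spare;

  explicit Rng(uint64_t seed) : g(seed), have_spare(false), spare(0.0) {}

  // uniform in [0, 1) with 53-bit resolution
  double unif() { return (g() >> 11) * (1.0 / 9007199254740992.0); }

  double unif_pos() {
    double u;
    do { u = unif(); } while (u <= 0.0);
    return u;
  }

  double norm() {
    if (have_spare) { have_spare = false; return spare; }
    double u1 = unif_pos(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double th = 6.283185307179586476925286766559 * u2;
    spare = r * std::sin(th);
    have_spare = true;
    return r * std::cos(th);
  }
};

#endif
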
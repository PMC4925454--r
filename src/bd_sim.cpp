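// Overdamped Brownian dynamics of a tethered ligand: Euler-Maruyama steps
// in the harmonic tether potential, absorbing capture sphere at |r| = a,
// radial mirror reflection at |r| = rstar. Self-contained xoshiro256++ RNG
// (seeded via splitmix64) so runs are reproducible independently of R's
// RNG state; normals by Marsaglia's polar method.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>

namespace {

struct Xoshiro256pp {
  uint64_t s[4];

  explicit Xoshiro256pp(uint64_t seed) {
    // splitmix64 expansion of the seed into the state
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }

  static uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform in (0, 1), never exactly 0
  double unif() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }

  bool has_spare = false;
  double spare = 0.0;

  double norm() {
    if (has_spare) {
      has_spare = false;
      return spare;
    }
    double u, v, s2;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      s2 = u * u + v * v;
    } while (s2 >= 1.0 || s2 == 0.0);
    double fac = std::sqrt(-2.0 * std::log(s2) / s2);
    spare = v * fac;
    has_spare = true;
    return u * fac;
  }
};

}  // namespace

// [[Rcpp::export]]
Rcpp::NumericVector bd_first_passage(double a, double rstar, double rstart,
                                     double r0sq, double D, double dt,
                                     int n_traj, double max_steps,
                                     int seed) {
  Xoshiro256pp rng(static_cast<uint64_t>(static_cast<int64_t>(seed)));
  Rcpp::NumericVector out(n_traj);
  const double drift = -D / r0sq * dt;
  const double noise = std::sqrt(2.0 * D * dt);
  const double a2 = a * a;
  const double rstar2 = rstar * rstar;
  const long long cap = static_cast<long long>(max_steps);

  for (int k = 0; k < n_traj; ++k) {
    // start uniformly on the sphere of radius rstart
    double x, y, z, s2;
    do {
      x = 2.0 * rng.unif() - 1.0;
      y = 2.0 * rng.unif() - 1.0;
      z = 2.0 * rng.unif() - 1.0;
      s2 = x * x + y * y + z * z;
    } while (s2 >= 1.0 || s2 < 1e-12);
    double inv = rstart / std::sqrt(s2);
    x *= inv; y *= inv; z *= inv;

    long long step = 0;
    double t_hit = -1.0;
    while (step < cap) {
      x += drift * x + noise * rng.norm();
      y += drift * y + noise * rng.norm();
      z += drift * z + noise * rng.norm();
      ++step;
      double r2 = x * x + y * y + z * z;
      if (r2 <= a2) {
        t_hit = static_cast<double>(step) * dt;
        break;
      }
      if (r2 > rstar2) {
        double r = std::sqrt(r2);
        double f = (2.0 * rstar - r) / r;
        x *= f; y *= f; z *= f;
      }
      if ((step & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
    }
    out[k] = (t_hit < 0.0) ? NA_REAL : t_hit;
  }
  return out;
}
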
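#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Self-contained counter-free RNG (xoshiro256++, seeded via splitmix64) so a
// multi-million-step trajectory does not pay R's RNG call overhead and stays
// bit-reproducible for a given integer seed.
namespace {

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97f4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
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
  inline double unif() {  // (0, 1)
    return ((next() >> 11) + 0.5) * 0x1.0p-53;
  }
  bool has_spare = false;
  double spare = 0.0;
  inline double norm() {  // Marsaglia polar method
    if (has_spare) { has_spare = false; return spare; }
    double u, v, q;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      q = u * u + v * v;
    } while (q >= 1.0 || q == 0.0);
    const double m = std::sqrt(-2.0 * std::log(q) / q);
    spare = v * m;
    has_spare = true;
    return u * m;
  }
};

struct Lefs {
  std::vector<int> L, R;
  inline int size() const { return (int)L.size(); }
  inline bool occupied(int site) const {
    for (size_t i = 0; i < L.size(); ++i)
      if (L[i] == site || R[i] == site) return true;
    return false;
  }
  inline void remove(int i) {
    L[i] = L.back(); L.pop_back();
    R[i] = R.back(); R.pop_back();
  }
};

}  // namespace

// Fused loop-extrusion + overdamped-Langevin engine.
// All monomer indices are 0-based. ctcf_dir: -1 blocks leftward arm movement
// off the site, +1 blocks rightward movement. kT = 1 throughout, so the
// backbone/LEF spring constant 3/b^2 gives an ideal chain with <r^2> = b^2
// per bond and `mobility` doubles as the monomer diffusion coefficient.
// [[Rcpp::export]]
List cpp_run_sim(NumericMatrix init_positions,
                 int anchor_a, int anchor_b,
                 IntegerVector ctcf_site, IntegerVector ctcf_dir,
                 NumericVector ctcf_prob,
                 IntegerMatrix init_lefs,
                 double loading_rate, double velocity, double unbinding_rate,
                 double bond_length, double lef_stiffness,
                 double mobility, double dt,
                 int burn_in_steps, int sample_interval, int n_samples,
                 IntegerVector keep, double seed,
                 bool excluded_volume, double ev_radius, double ev_strength) {
  const int n = init_positions.nrow();
  const int n_keep = keep.size();
  const double k_spring = 3.0 / (bond_length * bond_length);
  const double k_lef = lef_stiffness * k_spring;
  const double drift = mobility * dt;
  const double noise_sd = std::sqrt(2.0 * mobility * dt);
  const double p_move = velocity * dt;
  const double p_unbind = unbinding_rate * dt;

  if (p_move > 1.0)
    stop("rate overflow: velocity * dt = %f > 1", p_move);
  if (p_unbind > 1.0)
    stop("rate overflow: unbinding_rate * dt > 1");

  // CTCF capture probabilities indexed by site
  std::vector<double> block_left(n, 0.0), block_right(n, 0.0);
  for (int i = 0; i < ctcf_site.size(); ++i) {
    if (ctcf_dir[i] < 0) block_left[ctcf_site[i]] = ctcf_prob[i];
    else                 block_right[ctcf_site[i]] = ctcf_prob[i];
  }

  std::vector<double> x(n), y(n), z(n), fx(n), fy(n), fz(n);
  for (int i = 0; i < n; ++i) {
    x[i] = init_positions(i, 0);
    y[i] = init_positions(i, 1);
    z[i] = init_positions(i, 2);
  }

  Lefs lefs;
  for (int i = 0; i < init_lefs.nrow(); ++i) {
    lefs.L.push_back(init_lefs(i, 0));
    lefs.R.push_back(init_lefs(i, 1));
  }

  Xoshiro rng((uint64_t)seed);

  NumericVector out_pos((R_xlen_t)n_samples * n_keep * 3);
  NumericVector out_times(n_samples);
  IntegerVector out_bridged(n_samples);
  IntegerVector out_nlefs(n_samples);

  const long total_steps = (long)burn_in_steps + (long)n_samples * sample_interval;
  int sample_idx = 0;

  for (long step = 1; step <= total_steps; ++step) {
    // ---- 1D extrusion update -------------------------------------------
    for (int i = lefs.size() - 1; i >= 0; --i) {
      if (rng.unif() < p_unbind) { lefs.remove(i); continue; }
      // left arm moves left
      if (rng.unif() < p_move) {
        const int a = lefs.L[i], tgt = a - 1;
        if (tgt >= 0 && !lefs.occupied(tgt) &&
            !(block_left[a] > 0.0 && rng.unif() < block_left[a]))
          lefs.L[i] = tgt;
      }
      // right arm moves right
      if (rng.unif() < p_move) {
        const int a = lefs.R[i], tgt = a + 1;
        if (tgt < n && !lefs.occupied(tgt) &&
            !(block_right[a] > 0.0 && rng.unif() < block_right[a]))
          lefs.R[i] = tgt;
      }
    }
    // loading: expected new LEFs per step = loading_rate * dt * n_free (<< 1)
    const double lam = loading_rate * dt * (double)(n - 2 * lefs.size());
    if (lam > 0.0 && rng.unif() < lam) {
      for (int attempt = 0; attempt < 64; ++attempt) {
        const int s = (int)(rng.unif() * n);
        if (s < n && !lefs.occupied(s)) {
          lefs.L.push_back(s);
          lefs.R.push_back(s);
          break;
        }
      }
    }

    // ---- 3D Langevin update --------------------------------------------
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    for (int i = 0; i + 1 < n; ++i) {
      const double dxx = x[i + 1] - x[i];
      const double dyy = y[i + 1] - y[i];
      const double dzz = z[i + 1] - z[i];
      fx[i] += k_spring * dxx; fx[i + 1] -= k_spring * dxx;
      fy[i] += k_spring * dyy; fy[i + 1] -= k_spring * dyy;
      fz[i] += k_spring * dzz; fz[i + 1] -= k_spring * dzz;
    }
    for (int i = 0; i < lefs.size(); ++i) {
      const int a = lefs.L[i], b = lefs.R[i];
      if (b - a < 2) continue;  // backbone already bonds neighbours
      const double dxx = x[b] - x[a];
      const double dyy = y[b] - y[a];
      const double dzz = z[b] - z[a];
      fx[a] += k_lef * dxx; fx[b] -= k_lef * dxx;
      fy[a] += k_lef * dyy; fy[b] -= k_lef * dyy;
      fz[a] += k_lef * dzz; fz[b] -= k_lef * dzz;
    }
    if (excluded_volume) {
      const double r2c = ev_radius * ev_radius;
      for (int i = 0; i < n; ++i) {
        for (int j = i + 2; j < n; ++j) {
          const double dxx = x[j] - x[i];
          if (std::fabs(dxx) > ev_radius) continue;
          const double dyy = y[j] - y[i];
          const double dzz = z[j] - z[i];
          const double r2 = dxx * dxx + dyy * dyy + dzz * dzz;
          if (r2 < r2c && r2 > 1e-12) {
            // soft-core linear repulsion: |F| = ev_strength * (1 - r/rc)
            const double r = std::sqrt(r2);
            const double mag = ev_strength * (1.0 - r / ev_radius) / r;
            fx[i] -= mag * dxx; fx[j] += mag * dxx;
            fy[i] -= mag * dyy; fy[j] += mag * dyy;
            fz[i] -= mag * dzz; fz[j] += mag * dzz;
          }
        }
      }
    }
    for (int i = 0; i < n; ++i) {
      x[i] += drift * fx[i] + noise_sd * rng.norm();
      y[i] += drift * fy[i] + noise_sd * rng.norm();
      z[i] += drift * fz[i] + noise_sd * rng.norm();
    }

    // ---- sampling -------------------------------------------------------
    if (step > burn_in_steps && (step - burn_in_steps) % sample_interval == 0) {
      bool bridged = false;
      for (int i = 0; i < lefs.size(); ++i)
        if (lefs.L[i] == anchor_a && lefs.R[i] == anchor_b) { bridged = true; break; }
      for (int kk = 0; kk < n_keep; ++kk) {
        const int m = keep[kk];
        if (!std::isfinite(x[m]) || !std::isfinite(y[m]) || !std::isfinite(z[m]))
          stop("numerical instability: non-finite coordinate at step %ld "
               "(monomer %d); reduce timestep or mobility", step, m);
        out_pos[sample_idx + (R_xlen_t)n_samples * kk] = x[m];
        out_pos[sample_idx + (R_xlen_t)n_samples * (n_keep + kk)] = y[m];
        out_pos[sample_idx + (R_xlen_t)n_samples * (2 * n_keep + kk)] = z[m];
      }
      out_times[sample_idx] = step * dt;
      out_bridged[sample_idx] = bridged ? 1 : 0;
      out_nlefs[sample_idx] = lefs.size();
      ++sample_idx;
    }
    if (step % 200000 == 0) Rcpp::checkUserInterrupt();
  }

  out_pos.attr("dim") = IntegerVector::create(n_samples, n_keep, 3);

  NumericMatrix final_pos(n, 3);
  for (int i = 0; i < n; ++i) {
    final_pos(i, 0) = x[i];
    final_pos(i, 1) = y[i];
    final_pos(i, 2) = z[i];
  }
  IntegerMatrix final_lefs(lefs.size(), 2);
  for (int i = 0; i < lefs.size(); ++i) {
    final_lefs(i, 0) = lefs.L[i];
    final_lefs(i, 1) = lefs.R[i];
  }

  return List::create(_["positions"] = out_pos,
                      _["times"] = out_times,
                      _["bridged"] = out_bridged,
                      _["n_lefs"] = out_nlefs,
                      _["final_positions"] = final_pos,
                      _["final_lefs"] = final_lefs);
}
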
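// Layered-slab photon Monte Carlo with momentum-transfer bookkeeping.
//
// Scattering-only transport: absorption is applied analytically afterwards
// through the per-layer path lengths (white Monte Carlo), so one photon set
// serves arbitrary (mua, Db) re-weightings. Henyey-Greenstein phase
// function, Fresnel reflection at the mismatched top surface, absorbing
// bottom/side boundaries. Uses R's RNG so runs are reproducible under
// set.seed().

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// xoshiro256+ PRNG: much cheaper than going through R's RNG in the inner
// loop; seeded deterministically from the R-side seed via splitmix64
namespace {
struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    for (int i = 0; i < 4; ++i) {
      seed += 0x9e3779b97f4a7c15ULL;
      uint64_t z = seed;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline double next() {
    // uniform in (0, 1); never exactly 0 (the +1 below)
    uint64_t r = s[0] + s[3];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return ((r >> 11) + 1) * 0x1.0p-53;
  }
};
} // namespace

static inline double hg_cos(double g, double u) {
  // Henyey-Greenstein deviate for cos(theta)
  if (std::fabs(g) < 1e-6) return 2.0 * u - 1.0;
  double f = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  return (1.0 + g * g - f * f) / (2.0 * g);
}

static inline double fresnel_R(double n_rel, double ci) {
  // unpolarized reflectance, incidence cosine ci (>0), n_rel = n_in/n_out
  double s2 = n_rel * n_rel * (1.0 - ci * ci);
  if (s2 >= 1.0) return 1.0;  // total internal reflection
  double ct = std::sqrt(1.0 - s2);
  double rs = (n_rel * ci - ct) / (n_rel * ci + ct);
  double rp = (n_rel * ct - ci) / (n_rel * ct + ci);
  return 0.5 * (rs * rs + rp * rp);
}

// [[Rcpp::export(name = ".mc_simulate")]]
List mc_simulate(int n_photons,
                 NumericVector boundaries,   // z1, z2, z3 cumulative, mm
                 NumericVector mus,          // scattering coeff per layer, mm^-1
                 double g_anis,
                 double n_in, double n_out,
                 double src_radius,          // flat beam radius, mm
                 NumericVector det_rho,      // ring centre radii
                 NumericVector det_rad,      // ring half-widths
                 double r_kill,              // absorbing side boundary radius
                 double max_path,            // total path cap, mm
                 int seed) {
  const int nL = boundaries.size();
  const int nD = det_rho.size();
  const double n_rel = n_in / n_out;
  const double crit2 = 1.0 - 1.0 / (n_rel * n_rel); // sin^2 of critical angle
  std::vector<double> det_lo(nD), det_hi(nD);
  for (int d = 0; d < nD; ++d) {
    det_lo[d] = det_rho[d] - det_rad[d];
    det_hi[d] = det_rho[d] + det_rad[d];
  }
  std::vector<int> out_det;
  std::vector<double> out_L, out_Y;  // nL entries per detected photon
  Xoshiro rng((uint64_t)(uint32_t)seed);

  for (int ph = 0; ph < n_photons; ++ph) {
    // launch: uniform over source disk, pointing +z
    double r0 = src_radius * std::sqrt(rng.next());
    double phi0 = 2.0 * M_PI * rng.next();
    double x = r0 * std::cos(phi0), y = r0 * std::sin(phi0), z = 0.0;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    int layer = 0;
    double total = 0.0;
    std::vector<double> L(nL, 0.0), Y(nL, 0.0);
    bool alive = true;

    while (alive) {
      double s = -std::log(rng.next()) / mus[layer];
      // propagate, handling layer-plane crossings within the sampled
      // optical depth (all layers share n, so no internal refraction)
      while (true) {
        double z_top = (layer == 0) ? 0.0 : boundaries[layer - 1];
        double z_bot = boundaries[layer];
        double d_bound = (uz > 0.0) ? (z_bot - z) / uz
                       : (uz < 0.0) ? (z_top - z) / uz
                                    : R_PosInf;
        if (s < d_bound) {
          x += ux * s; y += uy * s; z += uz * s;
          L[layer] += s; total += s;
          break;
        }
        // step to the boundary plane
        x += ux * d_bound; y += uy * d_bound; z += uz * d_bound;
        L[layer] += d_bound; total += d_bound;
        double rem_tau = (s - d_bound) * mus[layer];  // leftover optical depth
        if (uz < 0.0 && layer == 0) {
          // top surface: Fresnel decision
          double ci = -uz;
          double R = (1.0 - ci * ci >= crit2) ? 1.0 : fresnel_R(n_rel, ci);
          if (rng.next() < R) {
            uz = -uz;
            s = rem_tau / mus[layer];
            continue;
          }
          // escapes: detected?
          double r = std::sqrt(x * x + y * y);
          for (int d = 0; d < nD; ++d) {
            if (r >= det_lo[d] && r <= det_hi[d]) {
              out_det.push_back(d + 1);
              for (int i = 0; i < nL; ++i) out_L.push_back(L[i]);
              for (int i = 0; i < nL; ++i) out_Y.push_back(Y[i]);
              break;
            }
          }
          alive = false;
          break;
        }
        if (uz > 0.0 && layer == nL - 1) { alive = false; break; } // bottom
        layer += (uz > 0.0) ? 1 : -1;
        s = rem_tau / mus[layer];
      }
      if (!alive) break;
      if (total > max_path || x * x + y * y > r_kill * r_kill) break;
      // scatter: HG polar angle; azimuth by rejection (trig-free)
      double ct = hg_cos(g_anis, rng.next());
      Y[layer] += 1.0 - ct;
      double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
      double cp, sp;
      for (;;) {
        double a = 2.0 * rng.next() - 1.0, b = 2.0 * rng.next() - 1.0;
        double s2 = a * a + b * b;
        if (s2 > 0.0 && s2 < 1.0) {
          cp = (a * a - b * b) / s2;
          sp = 2.0 * a * b / s2;
          break;
        }
      }
      double nux, nuy, nuz;
      if (std::fabs(uz) > 0.99999) {
        nux = st * cp; nuy = st * sp; nuz = ct * ((uz > 0) ? 1.0 : -1.0);
      } else {
        double den = std::sqrt(1.0 - uz * uz);
        nux = st * (ux * uz * cp - uy * sp) / den + ux * ct;
        nuy = st * (uy * uz * cp + ux * sp) / den + uy * ct;
        nuz = -st * cp * den + uz * ct;
      }
      ux = nux; uy = nuy; uz = nuz;
    }
  }

  int np = out_det.size();
  IntegerVector det(np);
  NumericMatrix Lm(np, nL), Ym(np, nL);
  for (int i = 0; i < np; ++i) {
    det[i] = out_det[i];
    for (int j = 0; j < nL; ++j) {
      Lm(i, j) = out_L[i * nL + j];
      Ym(i, j) = out_Y[i * nL + j];
    }
  }
  return List::create(_["detector"] = det, _["L"] = Lm, _["Y"] = Ym);
}

// [[Rcpp::export(name = ".mc_g1_weights")]]
NumericVector mc_g1_weights(NumericMatrix L, NumericMatrix Y,
                            NumericVector mua, NumericVector Db,
                            NumericVector tau, double k0) {
  // G1(tau) = mean_s exp(-(k0^2/3) sum_i Y_si <dr^2(tau)>_i)
  //                  exp(-sum_i mua_i L_si),   <dr^2>_i = 6 Db_i tau
  const int np = L.nrow(), nL = L.ncol(), nt = tau.size();
  std::vector<double> wabs(np), ydb(np);
  for (int s = 0; s < np; ++s) {
    double a = 0.0, d = 0.0;
    for (int i = 0; i < nL; ++i) {
      a += mua[i] * L(s, i);
      d += Y(s, i) * Db[i];
    }
    wabs[s] = std::exp(-a);
    ydb[s] = d;
  }
  NumericVector out(nt);
  for (int t = 0; t < nt; ++t) {
    double pref = k0 * k0 / 3.0 * 6.0 * tau[t];
    double acc = 0.0;
    for (int s = 0; s < np; ++s) acc += wabs[s] * std::exp(-pref * ydb[s]);
    out[t] = acc / np;
  }
  return out;
}
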
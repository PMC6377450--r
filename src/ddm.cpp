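// Wiener first-passage-time numerics for the 7-parameter diffusion model.
//
// Internally everything is rescaled to a unit diffusion coefficient
// (v/s, a/s, z/s), which leaves all observables unchanged.  Densities and
// CDFs use adaptive small-time / large-time series with absolute truncation
// error <= `tol` per evaluation.  Across-trial variability: the Normal drift
// mixture is integrated in closed form for the density and by Gauss-Hermite
// quadrature for the CDF / choice probability; uniform starting-point and
// non-decision-time ranges use Gauss-Legendre quadrature (nodes supplied
// from R).

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static const double SQRT_2PI = 2.5066282746310002;

// ---------------------------------------------------------------------------
// choice probability, lower boundary, unit diffusion: start z in (0, a)
static double pchoice_lower(double v, double a, double z) {
  if (std::fabs(v) < 1e-10) return 1.0 - z / a;
  if (v > 0) {
    double num = std::expm1(-2.0 * v * z) - std::expm1(-2.0 * v * a);
    double den = -std::expm1(-2.0 * v * a);
    return num / den;
  }
  // v < 0: scaled form, exponents stay negative
  return std::expm1(2.0 * v * (a - z)) / std::expm1(2.0 * v * a);
}

// ---------------------------------------------------------------------------
// series sums S(t) with the drift-dependent prefactor stripped off:
//   f_lower(t) = pref * S(t),  pref = exp(-v*z - v^2 t / 2) (or its
//   closed-form Normal-mixture generalisation).
// small-time: S = (1/sqrt(2 pi t^3)) sum_k (z + 2ka) exp(-(z+2ka)^2 / 2t)
// large-time: S = (pi/a^2) sum_k k exp(-k^2 pi^2 t / (2 a^2)) sin(k pi w)

static double series_small(double t, double a, double z, double tol) {
  const double c0 = 1.0 / (SQRT_2PI * std::pow(t, 1.5));
  double sum = z * std::exp(-z * z / (2.0 * t));
  for (int k = 1; k < 200; ++k) {
    double zp = z + 2.0 * k * a;
    double zm = z - 2.0 * k * a;
    double tp = zp * std::exp(-zp * zp / (2.0 * t));
    double tm = zm * std::exp(-zm * zm / (2.0 * t));
    sum += tp + tm;
    if (std::fabs(tp) + std::fabs(tm) < tol / c0) break;
  }
  return c0 * sum;
}

static double series_large(double t, double a, double z, double tol) {
  const double w = z / a;
  const double c0 = M_PI / (a * a);
  const double lam = M_PI * M_PI * t / (2.0 * a * a);
  double sum = 0.0;
  int small_in_a_row = 0;
  for (int k = 1; k < 10000; ++k) {
    double env = k * std::exp(-lam * k * k);
    sum += env * std::sin(k * M_PI * w);
    if (env < tol / c0) { if (++small_in_a_row >= 2) break; }
    else small_in_a_row = 0;
  }
  return c0 * sum;
}

// density at the lower boundary, unit diffusion, fixed drift v, no Ter
static double wfpt_pdf_lower(double t, double v, double a, double w,
                             double tol) {
  if (t <= 0.0) return 0.0;
  double z = w * a;
  double pref = std::exp(-v * z - v * v * t / 2.0);
  double stol = tol / std::max(pref, 1e-10);
  double tt = t / (a * a);
  double S = (tt <= 0.35) ? series_small(t, a, z, stol)
                          : series_large(t, a, z, stol);
  double f = pref * S;
  return (f > 0.0) ? f : 0.0;
}

// density with the Normal drift mixture integrated in closed form:
// mean drift mu, SD eta (>= 0)
static double wfpt_pdf_lower_eta(double t, double mu, double eta, double a,
                                 double w, double tol) {
  if (t <= 0.0) return 0.0;
  double z = w * a;
  double pref;
  if (eta <= 0.0) {
    pref = std::exp(-mu * z - mu * mu * t / 2.0);
  } else {
    double e2 = eta * eta;
    pref = std::exp((e2 * z * z - 2.0 * mu * z - mu * mu * t) /
                    (2.0 * (1.0 + e2 * t))) / std::sqrt(1.0 + e2 * t);
  }
  double stol = tol / std::max(pref, 1e-10);
  double tt = t / (a * a);
  double S = (tt <= 0.35) ? series_small(t, a, z, stol)
                          : series_large(t, a, z, stol);
  double f = pref * S;
  return (f > 0.0) ? f : 0.0;
}

// ---------------------------------------------------------------------------
// CDF at the lower boundary, unit diffusion, fixed drift, no Ter.
// Small-time: image expansion in single-barrier inverse-Gaussian CDF terms;
// each term evaluated in log space for stability.
// G(t; d, m) = Phi((m t - d)/sqrt t) + exp(2 m d) Phi(-(m t + d)/sqrt t)

static inline double exp_pnorm(double lg, double x) {
  // exp(lg) * Phi(x), computed stably
  if (lg < 600.0)
    return std::exp(lg) * 0.5 * std::erfc(-x * M_SQRT1_2);
  return std::exp(lg + R::pnorm(x, 0.0, 1.0, 1, 1));
}

static double cdf_small(double t, double v, double a, double z, double tol) {
  double st = std::sqrt(t);
  double F = 0.0;
  for (int k = 0; k < 200; ++k) {
    // k >= 0 image at z + 2ka, weight exp(2 v k a), drift -v
    double zk = z + 2.0 * k * a;
    double t1 = exp_pnorm(2.0 * v * k * a, (-v * t - zk) / st);
    double t2 = exp_pnorm(2.0 * v * k * a - 2.0 * v * zk, (v * t - zk) / st);
    double inc = t1 + t2;
    double dec = 0.0;
    if (k >= 1) {
      // negative image at distance d = 2ka - z, weight -exp(-2 v k a), drift +v
      double d = 2.0 * k * a - z;
      double u1 = exp_pnorm(-2.0 * v * k * a, (v * t - d) / st);
      double u2 = exp_pnorm(-2.0 * v * k * a + 2.0 * v * d, -(v * t + d) / st);
      dec = u1 + u2;
    }
    F += inc - dec;
    if (k >= 1 && inc < tol && dec < tol) break;
  }
  return F;
}

static double cdf_large(double t, double v, double a, double z, double tol) {
  double w = z / a;
  double P = pchoice_lower(v, a, z);
  double c0 = (M_PI / (a * a)) * std::exp(-v * z);
  double tail = 0.0;
  int small_in_a_row = 0;
  for (int k = 1; k < 10000; ++k) {
    double alpha = (v * v + k * k * M_PI * M_PI / (a * a)) / 2.0;
    double env = c0 * k * std::exp(-alpha * t) / alpha;
    tail += env * std::sin(k * M_PI * w);
    if (std::fabs(env) < tol) { if (++small_in_a_row >= 2) break; }
    else small_in_a_row = 0;
  }
  double F = P - tail;
  if (F < 0.0) F = 0.0;
  if (F > P) F = P;
  return F;
}

static double wfpt_cdf_lower(double t, double v, double a, double w,
                             double tol) {
  if (t <= 0.0) return 0.0;
  double z = w * a;
  double tt = t / (a * a);
  return (tt <= 0.35) ? cdf_small(t, v, a, z, tol)
                      : cdf_large(t, v, a, z, tol);
}

// lower-boundary CDF averaged over a set of drift nodes (Normal drift
// mixture).  For the large-time branch the eigen-series terms do not depend
// on drift, so they are computed once and reused across nodes.
static double cdf_mix_drift(double t, double a, double w,
                            const std::vector<double>& vn,
                            const std::vector<double>& wn, double tol) {
  if (t <= 0.0) return 0.0;
  double z = w * a;
  double tt = t / (a * a);
  size_t m = vn.size();
  if (tt <= 0.15) {
    double acc = 0.0;
    for (size_t i = 0; i < m; ++i)
      acc += wn[i] * cdf_small(t, vn[i], a, z, tol);
    return acc;
  }
  // precompute drift-independent series pieces
  const double lam = M_PI * M_PI * t / (2.0 * a * a);
  std::vector<double> bk, ck;
  int small_in_a_row = 0;
  for (int k = 1; k < 10000; ++k) {
    double env = k * std::exp(-lam * k * k);
    bk.push_back(env * std::sin(k * M_PI * w));
    ck.push_back(k * k * M_PI * M_PI / (a * a));
    if (env < tol * 0.1) { if (++small_in_a_row >= 2) break; }
    else small_in_a_row = 0;
  }
  const double c0 = M_PI / (a * a);
  double acc = 0.0;
  for (size_t i = 0; i < m; ++i) {
    double v = vn[i];
    double P = pchoice_lower(v, a, z);
    double pref = c0 * std::exp(-v * z - v * v * t / 2.0);
    double tail = 0.0;
    for (size_t k = 0; k < bk.size(); ++k)
      tail += bk[k] * 2.0 / (v * v + ck[k]);
    double F = P - pref * tail;
    if (F < 0.0) F = 0.0;
    if (F > P) F = P;
    acc += wn[i] * F;
  }
  return acc;
}

// ---------------------------------------------------------------------------
// quadrature-averaged quantities in natural units (diffusion coefficient s).
// upper boundary via reflection (v, w) -> (-v, 1 - w).

struct QuadSpec {
  // Gauss-Hermite (for Normal drift) and Gauss-Legendre on [-1/2, 1/2]
  // (for uniform sz, st) nodes and weights; empty when that variability is 0.
  std::vector<double> ghx, ghw, szx, szw, stx, stw;
};

static QuadSpec make_quad(double eta, double sz, double st,
                          NumericVector ghx, NumericVector ghw,
                          NumericVector glx, NumericVector glw) {
  QuadSpec q;
  if (eta > 0.0) {
    for (int i = 0; i < ghx.size(); ++i) { q.ghx.push_back(ghx[i]); q.ghw.push_back(ghw[i]); }
  } else { q.ghx.push_back(0.0); q.ghw.push_back(1.0); }
  if (sz > 0.0) {
    for (int i = 0; i < glx.size(); ++i) { q.szx.push_back(glx[i]); q.szw.push_back(glw[i]); }
  } else { q.szx.push_back(0.0); q.szw.push_back(1.0); }
  if (st > 0.0) {
    for (int i = 0; i < glx.size(); ++i) { q.stx.push_back(glx[i]); q.stw.push_back(glw[i]); }
  } else { q.stx.push_back(0.0); q.stw.push_back(1.0); }
  return q;
}

// full defective CDF at one boundary; t in seconds (includes Ter)
// [[Rcpp::export]]
NumericVector cpp_fpt_cdf(NumericVector t, bool upper, double v, double a,
                          double z_rel, double ter, double eta, double sz,
                          double st, double s, NumericVector ghx,
                          NumericVector ghw, NumericVector glx,
                          NumericVector glw, double tol) {
  double an = a / s, etan = eta / s, szn = sz / s;
  QuadSpec q = make_quad(etan, szn, st, ghx, ghw, glx, glw);
  // drift nodes of the Normal mixture, reflected for the upper boundary
  std::vector<double> vn(q.ghx.size()), wn(q.ghw.size());
  for (size_t k = 0; k < q.ghx.size(); ++k) {
    double vv = v / s + M_SQRT2 * etan * q.ghx[k];
    vn[k] = upper ? -vv : vv;
    wn[k] = q.ghw[k];
  }
  int nt = t.size();
  NumericVector out(nt);
  for (int it = 0; it < nt; ++it) {
    double acc = 0.0;
    for (size_t i = 0; i < q.stx.size(); ++i) {
      double td = t[it] - (ter + st * q.stx[i]);
      if (td <= 0.0) continue;
      for (size_t j = 0; j < q.szx.size(); ++j) {
        double z_abs = z_rel * an + szn * q.szx[j];
        double w = upper ? 1.0 - z_abs / an : z_abs / an;
        acc += q.stw[i] * q.szw[j] * cdf_mix_drift(td, an, w, vn, wn, tol);
      }
    }
    out[it] = acc;
  }
  return out;
}

// full defective density at one boundary (eta integrated in closed form)
// [[Rcpp::export]]
NumericVector cpp_fpt_pdf(NumericVector t, bool upper, double v, double a,
                          double z_rel, double ter, double eta, double sz,
                          double st, double s, NumericVector glx,
                          NumericVector glw, double tol) {
  double an = a / s, etan = eta / s, szn = sz / s;
  QuadSpec q = make_quad(0.0, szn, st, NumericVector(0), NumericVector(0),
                         glx, glw);
  int nt = t.size();
  NumericVector out(nt);
  for (int it = 0; it < nt; ++it) {
    double acc = 0.0;
    for (size_t i = 0; i < q.stx.size(); ++i) {
      double td = t[it] - (ter + st * q.stx[i]);
      if (td <= 0.0) continue;
      for (size_t j = 0; j < q.szx.size(); ++j) {
        double z_abs = z_rel * an + szn * q.szx[j];
        double w = z_abs / an;
        double wt = q.stw[i] * q.szw[j];
        double f = upper
          ? wfpt_pdf_lower_eta(td, -v / s, etan, an, 1.0 - w, tol)
          : wfpt_pdf_lower_eta(td, v / s, etan, an, w, tol);
        acc += wt * f;
      }
    }
    out[it] = acc;
  }
  return out;
}

// absorption probability at one boundary, with eta/sz variability
// [[Rcpp::export]]
double cpp_choice_prob(bool upper, double v, double a, double z_rel,
                       double eta, double sz, double s, NumericVector ghx,
                       NumericVector ghw, NumericVector glx,
                       NumericVector glw) {
  double an = a / s, etan = eta / s, szn = sz / s;
  QuadSpec q = make_quad(etan, szn, 0.0, ghx, ghw, glx, glw);
  double acc = 0.0;
  for (size_t j = 0; j < q.szx.size(); ++j) {
    double z_abs = z_rel * an + szn * q.szx[j];
    for (size_t k = 0; k < q.ghx.size(); ++k) {
      double vn = v / s + M_SQRT2 * etan * q.ghx[k];
      double wt = q.szw[j] * q.ghw[k];
      double P = pchoice_lower(vn, an, z_abs);
      acc += wt * (upper ? 1.0 - P : P);
    }
  }
  return acc;
}

// multinomial cell negative log-likelihood for quantile bins.
// edges_* are interior RT edges (possibly length 0); counts_* have
// length(edges) + 1 entries per boundary.
// [[Rcpp::export]]
double cpp_cell_negloglik(NumericVector counts_upper,
                          NumericVector counts_lower,
                          NumericVector edges_upper,
                          NumericVector edges_lower, double v, double a,
                          double z_rel, double ter, double eta, double sz,
                          double st, double s, NumericVector ghx,
                          NumericVector ghw, NumericVector glx,
                          NumericVector glw, double tol) {
  NumericVector Fu = cpp_fpt_cdf(edges_upper, true, v, a, z_rel, ter, eta,
                                 sz, st, s, ghx, ghw, glx, glw, tol);
  NumericVector Fl = cpp_fpt_cdf(edges_lower, false, v, a, z_rel, ter, eta,
                                 sz, st, s, ghx, ghw, glx, glw, tol);
  double Pu = cpp_choice_prob(true, v, a, z_rel, eta, sz, s, ghx, ghw, glx,
                              glw);
  double Pl = 1.0 - Pu;
  double nll = 0.0;
  int mu = edges_upper.size();
  for (int b = 0; b <= mu; ++b) {
    double lo = (b == 0) ? 0.0 : Fu[b - 1];
    double hi = (b == mu) ? Pu : Fu[b];
    double p = hi - lo;
    if (p < 1e-12) p = 1e-12;
    if (counts_upper[b] > 0) nll -= counts_upper[b] * std::log(p);
  }
  int ml = edges_lower.size();
  for (int b = 0; b <= ml; ++b) {
    double lo = (b == 0) ? 0.0 : Fl[b - 1];
    double hi = (b == ml) ? Pl : Fl[b];
    double p = hi - lo;
    if (p < 1e-12) p = 1e-12;
    if (counts_lower[b] > 0) nll -= counts_lower[b] * std::log(p);
  }
  return nll;
}

// ---------------------------------------------------------------------------
// Euler-Maruyama trial simulator with its own counter-free xoshiro256++ RNG
// (R's RNG is untouched; byte-identical reproducibility from the seed alone).

namespace rng {
struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    // splitmix64 expansion of the seed
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97F4A7C15ULL;
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
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  bool has_spare = false;
  double spare = 0.0;
  inline double norm() {
    if (has_spare) { has_spare = false; return spare; }
    double u, vv, q;
    do {
      u = 2.0 * unif() - 1.0;
      vv = 2.0 * unif() - 1.0;
      q = u * u + vv * vv;
    } while (q >= 1.0 || q == 0.0);
    double f = std::sqrt(-2.0 * std::log(q) / q);
    spare = vv * f; has_spare = true;
    return u * f;
  }
};
}  // namespace rng

// Simulate n trials; v and z_rel may be scalars or length-n vectors
// (per-trial conditions).  Returns matrix [rt, upper] with rt = NA for
// paths that did not absorb within t_max.
// When `correct` is true the absorbing boundaries are moved inward by
// 0.5826 * s * sqrt(dt) (continuity correction for the discrete-time
// first-passage bias).
// [[Rcpp::export]]
NumericMatrix cpp_sim_ddm(int n, NumericVector v, double a,
                          NumericVector z_rel, double ter, double eta,
                          double sz, double st, double s, double dt,
                          double t_max, double seed, bool correct) {
  rng::Xoshiro gen(static_cast<uint64_t>(seed));
  NumericMatrix out(n, 2);
  const double sdt = s * std::sqrt(dt);
  const double delta = correct ? 0.5826 * sdt : 0.0;
  const double lo = delta, hi = a - delta;
  const long max_steps = static_cast<long>(t_max / dt) + 1;
  const bool vec_v = v.size() > 1, vec_z = z_rel.size() > 1;
  for (int i = 0; i < n; ++i) {
    double mu = (vec_v ? v[i] : v[0]) + (eta > 0 ? eta * gen.norm() : 0.0);
    double zr = vec_z ? z_rel[i] : z_rel[0];
    double x = zr * a + (sz > 0 ? sz * (gen.unif() - 0.5) : 0.0);
    double ndt = ter + (st > 0 ? st * (gen.unif() - 0.5) : 0.0);
    double drift = mu * dt;
    long step = 0;
    int boundary = -1;
    while (step < max_steps) {
      ++step;
      x += drift + sdt * gen.norm();
      if (x >= hi) { boundary = 1; break; }
      if (x <= lo) { boundary = 0; break; }
    }
    if (boundary < 0) {
      out(i, 0) = NA_REAL;
      out(i, 1) = NA_REAL;
    } else {
      out(i, 0) = step * dt + ndt;
      out(i, 1) = boundary;
    }
  }
  return out;
}
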
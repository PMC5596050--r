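// Backward induction of the survival value function and Monte Carlo forward
// simulation of cohorts following the optimal policy.
//
// State layout: index = x + nf*(y + ny*w), x fastest; weather 0 = good,
// 1 = bad. Periods are 0-based; the horizon T is a daybreak. Behaviours are
// 1..6 (stored 1-based in the policy array; 0 = no feasible behaviour, which
// cannot occur under the mask rules).

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <cmath>
#include <random>
using namespace Rcpp;

namespace {

struct Model {
  int nf, ny, T, ppd, d_start, d_end, sigma_nodes, mode, shallow_nodes;
  int interp_mode;  // 0 linear, 1 Steffen monotone cubic
  double dx, Xmax, CRMp, gamma_, delta_, eps, CWU_per, xcr, alpha, pGG, pBB;
  std::vector<double> fat, xC, mu, lambda, Gp, beta_day, end_p;
  double bhd, bhn, brn;  // per-period hazards: hypothermic day/night, night rest
  std::vector<double> massm;            // mass multiplier per fat node
  std::vector<double> costF[3];         // per-node cost, behaviours 1..3
  std::vector<double> betaD[3];         // per-node daylight hazard, behaviours 1..3
};

Model build_model(const List& P) {
  Model m;
  m.nf = as<int>(P["nf"]); m.ny = as<int>(P["ny"]); m.T = as<int>(P["T"]);
  m.ppd = as<int>(P["ppd"]);
  m.d_start = as<int>(P["d_start"]); m.d_end = as<int>(P["d_end"]);
  m.sigma_nodes = as<int>(P["sigma_nodes"]);
  m.mode = as<int>(P["mode"]);
  m.shallow_nodes = as<int>(P["shallow_nodes"]);
  m.interp_mode = as<int>(P["interp_mode"]);
  m.dx = as<double>(P["dx"]); m.Xmax = as<double>(P["Xmax"]);
  m.CRMp = as<double>(P["CRMp"]); m.gamma_ = as<double>(P["gamma"]);
  m.delta_ = as<double>(P["delta"]); m.eps = as<double>(P["eps"]);
  m.CWU_per = as<double>(P["CWU_per"]);
  m.xcr = as<double>(P["xcr"]); m.alpha = as<double>(P["alpha"]);
  m.pGG = as<double>(P["pGG"]); m.pBB = as<double>(P["pBB"]);
  m.fat = as<std::vector<double>>(P["fat"]);
  m.xC = as<std::vector<double>>(P["xC"]);
  m.mu = as<std::vector<double>>(P["mu"]);
  m.lambda = as<std::vector<double>>(P["lambda"]);
  m.Gp = as<std::vector<double>>(P["Gp"]);
  m.beta_day = as<std::vector<double>>(P["beta_day"]);
  m.end_p = as<std::vector<double>>(P["end_p"]);
  m.bhd = as<double>(P["bhd"]); m.bhn = as<double>(P["bhn"]);
  m.brn = as<double>(P["brn"]);

  m.massm.resize(m.nf);
  for (int k = 0; k < m.nf; ++k) {
    double x = m.fat[k];
    m.massm[k] = (x > m.xcr) ? 1.0 + std::pow((x - m.xcr) / m.xcr, m.alpha) : 1.0;
  }
  for (int i = 0; i < 3; ++i) {
    m.costF[i].resize(m.nf);
    m.betaD[i].resize(m.nf);
    for (int k = 0; k < m.nf; ++k) {
      m.costF[i][k] = m.CRMp * (1.0 + m.mu[i] + m.mu[i] * m.fat[k] / m.Xmax);
      double b = m.beta_day[i] * m.massm[k];
      m.betaD[i][k] = b < 1.0 ? b : 1.0 - 1e-12;
    }
  }
  return m;
}

inline double mass_mult(const Model& m, double x) {
  return (x > m.xcr) ? 1.0 + std::pow((x - m.xcr) / m.xcr, m.alpha) : 1.0;
}

inline double interp(const double* F, const Model& m, double x) {
  if (x <= 0.0) return 0.0;
  if (x >= m.Xmax) return F[m.nf - 1];
  double u = x / m.dx;
  int k = (int)u;
  if (k >= m.nf - 1) return F[m.nf - 1];
  double f = u - k;
  return F[k] + f * (F[k + 1] - F[k]);
}

// Steffen (1990) monotonicity-limited slopes on a unit-spaced grid. Repeated
// linear interpolation of the near-deterministic night-time fat decline acts
// as numerical diffusion (SD ~ sqrt(n/6) grid steps per night) and badly
// biases survival on the baseline grid; a monotone cubic interpolant removes
// that smearing while never overshooting the bracketing node values.
inline void steffen_slopes(const double* F, double* D, int n) {
  if (n < 3) { for (int i = 0; i < n; ++i) D[i] = (n == 2) ? F[1] - F[0] : 0.0; return; }
  double s_prev = F[1] - F[0];
  D[0] = s_prev;  // one-sided, clipped below
  if ((D[0] > 0 && D[0] > 3 * s_prev) || (D[0] < 0 && D[0] < 3 * s_prev))
    D[0] = 3 * s_prev;
  for (int i = 1; i < n - 1; ++i) {
    double s_i = F[i + 1] - F[i];
    if (s_prev * s_i <= 0.0) D[i] = 0.0;
    else {
      double p = 0.5 * (s_prev + s_i);
      double lim = 2.0 * std::min(std::fabs(s_prev), std::fabs(s_i));
      D[i] = (std::fabs(p) > lim) ? (p > 0 ? lim : -lim) : p;
    }
    s_prev = s_i;
  }
  D[n - 1] = s_prev;
}

// cubic Hermite evaluation with unit spacing and Steffen slopes
inline double interp_cubic(const double* F, const double* D, const Model& m,
                           double x) {
  if (x <= 0.0) return 0.0;
  if (x >= m.Xmax) return F[m.nf - 1];
  double u = x / m.dx;
  int k = (int)u;
  if (k >= m.nf - 1) return F[m.nf - 1];
  double f = u - k;
  double f2 = f * f, f3 = f2 * f;
  return (2 * f3 - 3 * f2 + 1) * F[k] + (f3 - 2 * f2 + f) * D[k] +
         (-2 * f3 + 3 * f2) * F[k + 1] + (f3 - f2) * D[k + 1];
}

// is behaviour i (1..6) feasible at depth node y at day/night?
inline bool feasible(const Model& m, int i, int y, bool is_day) {
  switch (i) {
    case 1: case 2: return is_day && y < m.shallow_nodes;
    case 3: return y == 0;
    case 4: return y < m.ny - 1;
    case 5: case 6: return y > 0;
  }
  return false;
}

inline int next_y(const Model& m, int i, int y) {
  if (i == 4) { int yn = y + m.sigma_nodes; return yn > m.ny - 1 ? m.ny - 1 : yn; }
  if (i == 5) { int yn = y - m.sigma_nodes; return yn < 0 ? 0 : yn; }
  return y;
}

// daylight hazard for hypothermic-class behaviours at post-decision depth yn;
// beta3x = mass-dependent resting hazard at the bird's fat load
inline double hypo_day_hazard(const Model& m, int yn, double beta3x) {
  double h;
  if (m.mode == 0) h = m.bhd;
  else if (m.mode == 1) h = beta3x + (double)yn / (m.ny - 1) * m.bhd;
  else h = beta3x;
  return h < 1.0 ? h : 1.0 - 1e-12;
}

// hazard for behaviour i at fat x (continuous), post-decision depth yn
inline double hazard_at(const Model& m, int i, double x, int yn, bool is_day) {
  if (i <= 3) {
    if (!is_day) return m.brn;  // only behaviour 3 is feasible at night
    double b = m.beta_day[i - 1] * mass_mult(m, x);
    return b < 1.0 ? b : 1.0 - 1e-12;
  }
  if (!is_day) return m.bhn;
  return hypo_day_hazard(m, yn, m.beta_day[2] * mass_mult(m, x));
}

// per-period cost (before the weather factor) and flat surcharge
inline void cost_of(const Model& m, int i, double x, int yn,
                    double& cost, double& surcharge) {
  surcharge = 0.0;
  if (i <= 3) {
    cost = m.CRMp * (1.0 + m.mu[i - 1] + m.mu[i - 1] * x / m.Xmax);
  } else {
    double f = (double)yn / (m.ny - 1);
    cost = m.CRMp * (1.0 - m.eps * f);
    if (i == 5) surcharge = m.CWU_per;
  }
}

inline double value_at(const Model& m, const double* F, const double* D,
                       double x) {
  return m.interp_mode == 1 ? interp_cubic(F, D, m, x) : interp(F, m, x);
}

}  // namespace

// [[Rcpp::export]]
List cpp_solve(List P, IntegerVector keep_ts) {
  Model m = build_model(P);
  const int S = m.nf * m.ny * 2;
  std::vector<double> Fnext(S), Fcur(S);
  RawVector policy((R_xlen_t)S * m.T);
  NumericVector Fkeep((R_xlen_t)S * keep_ts.size());
  std::vector<int> keep_idx(m.T + 1, -1);
  for (int k = 0; k < keep_ts.size(); ++k) keep_idx[keep_ts[k]] = k;

  // terminal condition at t = T (a daybreak): survive iff fat covers x_C(y)
  for (int w = 0; w < 2; ++w)
    for (int y = 0; y < m.ny; ++y)
      for (int k = 0; k < m.nf; ++k)
        Fnext[k + m.nf * (y + m.ny * w)] =
            (k > 0 && m.fat[k] >= m.xC[y]) ? 1.0 : 0.0;  // fat 0 = starved
  if (keep_idx[m.T] >= 0)
    std::copy(Fnext.begin(), Fnext.end(), Fkeep.begin() + (R_xlen_t)S * keep_idx[m.T]);

  std::vector<double> score(m.nf), best(m.nf), bestBeta(m.nf);
  std::vector<int> bestI(m.nf);
  std::vector<double> slopes(S, 0.0);

  for (int t = m.T - 1; t >= 0; --t) {
    if (m.interp_mode == 1)
      for (int r = 0; r < 2 * m.ny; ++r)
        steffen_slopes(Fnext.data() + m.nf * r, slopes.data() + m.nf * r, m.nf);
    int pod = t % m.ppd;
    bool is_day = pod >= m.d_start && pod < m.d_end;
    double pe = m.end_p[t];

    for (int w = 0; w < 2; ++w) {
      double p_stay = (w == 0) ? m.pGG : m.pBB;
      for (int y = 0; y < m.ny; ++y) {
        std::fill(best.begin(), best.end(), -1.0);
        std::fill(bestBeta.begin(), bestBeta.end(), 2.0);
        std::fill(bestI.begin(), bestI.end(), 0);

        for (int i = 1; i <= 6; ++i) {
          if (!feasible(m, i, y, is_day)) continue;
          int yn = next_y(m, i, y);
          double lam = m.lambda[i - 1];
          bool forage = (i <= 2);
          double gs = forage ? m.Gp[i - 1] : 0.0;
          double gf = gs * m.delta_;
          double sur = (i == 5) ? m.CWU_per : 0.0;
          std::fill(score.begin(), score.end(), 0.0);

          for (int b = 0; b < 2; ++b) {          // weather branch
            int wn = (b == 0) ? w : 1 - w;
            double pw = (b == 0) ? p_stay : 1.0 - p_stay;
            double gfac = (wn == 1) ? m.gamma_ : 1.0;
            const double* Frow = Fnext.data() + m.nf * (yn + m.ny * wn);
            const double* Drow = slopes.data() + m.nf * (yn + m.ny * wn);
            if (i <= 3) {
              const std::vector<double>& cv = m.costF[i - 1];
              if (forage && lam < 1.0) {
                for (int k = 0; k < m.nf; ++k) {
                  double base = m.fat[k] - cv[k] * gfac;
                  score[k] += pw * (lam * value_at(m, Frow, Drow, base + gs) +
                                    (1.0 - lam) * value_at(m, Frow, Drow, base + gf));
                }
              } else {
                for (int k = 0; k < m.nf; ++k)
                  score[k] += pw * value_at(m, Frow, Drow, m.fat[k] + gs - cv[k] * gfac);
              }
            } else {
              double f = (double)yn / (m.ny - 1);
              double c = m.CRMp * (1.0 - m.eps * f);
              for (int k = 0; k < m.nf; ++k)
                score[k] += pw * value_at(m, Frow, Drow, m.fat[k] - c * gfac - sur);
            }
          }

          // apply the survival factor and keep the argmax
          if (i <= 3 && is_day) {
            const std::vector<double>& bv = m.betaD[i - 1];
            for (int k = 0; k < m.nf; ++k) {
              double v = (1.0 - bv[k]) * score[k];
              if (v > best[k] || (v == best[k] && bv[k] < bestBeta[k])) {
                best[k] = v; bestBeta[k] = bv[k]; bestI[k] = i;
              }
            }
          } else if (i <= 3) {  // night rest, safe-habitat risk class
            for (int k = 0; k < m.nf; ++k) {
              double v = (1.0 - m.brn) * score[k];
              if (v > best[k] || (v == best[k] && m.brn < bestBeta[k])) {
                best[k] = v; bestBeta[k] = m.brn; bestI[k] = i;
              }
            }
          } else {
            for (int k = 0; k < m.nf; ++k) {
              double bb = is_day ? hypo_day_hazard(m, yn, m.betaD[2][k]) : m.bhn;
              double v = (1.0 - bb) * score[k];
              if (v > best[k] || (v == best[k] && bb < bestBeta[k])) {
                best[k] = v; bestBeta[k] = bb; bestI[k] = i;
              }
            }
          }
        }

        double* Fout = Fcur.data() + m.nf * (y + m.ny * w);
        Rbyte* pol = &policy[(R_xlen_t)S * t + m.nf * (y + m.ny * w)];
        if (pe > 0.0) {
          for (int k = 0; k < m.nf; ++k) {
            double phi = (m.fat[k] >= m.xC[y]) ? 1.0 : 0.0;
            Fout[k] = pe * phi + (1.0 - pe) * best[k];
            pol[k] = (Rbyte)bestI[k];
          }
        } else {
          for (int k = 0; k < m.nf; ++k) {
            Fout[k] = best[k];
            pol[k] = (Rbyte)bestI[k];
          }
        }
        // fat exhausted means death regardless of behaviour
        Fout[0] = 0.0;
      }
    }
    if (keep_idx[t] >= 0)
      std::copy(Fcur.begin(), Fcur.end(), Fkeep.begin() + (R_xlen_t)S * keep_idx[t]);
    std::swap(Fcur, Fnext);
    if (t % 2048 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["policy"] = policy, _["F_keep"] = Fkeep);
}

namespace {
inline std::uint64_t splitmix64(std::uint64_t z) {
  z += 0x9E3779B97F4A7C15ULL;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}
struct Rng {
  std::mt19937_64 gen;
  Rng(std::uint64_t seed, std::uint64_t stream) {
    std::uint64_t s = splitmix64(seed * 0x9E3779B97F4A7C15ULL + stream + 1);
    gen.seed(s);
    gen.discard(8);
  }
  double u() { return (gen() >> 11) * (1.0 / 9007199254740992.0); }
};
}  // namespace

// Outcome codes: 0 survived winter end, 1 killed by predator, 2 starved,
// 3 alive at winter end but below the warm-up fat requirement.
// [[Rcpp::export]]
List cpp_simulate(List P, RawVector policy, int n_birds, double seed,
                  IntegerVector record_ts, double x_start, int start_t) {
  Model m = build_model(P);
  const int S = m.nf * m.ny * 2;
  if ((R_xlen_t)S * m.T != policy.size())
    stop("policy does not match the model's state-grid dimensions");

  std::vector<int> rec_col(m.T + 1, -1);
  for (int k = 0; k < record_ts.size(); ++k) rec_col[record_ts[k]] = k;
  int nrec = record_ts.size();

  NumericMatrix rec_fat(n_birds, nrec);
  IntegerMatrix rec_y(n_birds, nrec), rec_beh(n_birds, nrec),
      rec_w(n_birds, nrec), rec_alive(n_birds, nrec);
  std::fill(rec_fat.begin(), rec_fat.end(), NA_REAL);
  std::fill(rec_y.begin(), rec_y.end(), NA_INTEGER);
  std::fill(rec_beh.begin(), rec_beh.end(), NA_INTEGER);
  std::fill(rec_w.begin(), rec_w.end(), NA_INTEGER);
  std::fill(rec_alive.begin(), rec_alive.end(), 0);

  IntegerVector outcome(n_birds), end_t(n_birds);

  for (int b = 0; b < n_birds; ++b) {
    Rng rng((std::uint64_t)seed, (std::uint64_t)b);
    double x = x_start;
    int y = 0, w = 0, t = start_t, out = -1;

    while (t <= m.T) {
      // winter may end at candidate daybreaks (certain at the horizon T)
      double pe = m.end_p[t];
      bool ends = (t == m.T) || (pe > 0.0 && rng.u() < pe);
      int col = rec_col[t];
      if (col >= 0) {
        rec_fat(b, col) = x; rec_y(b, col) = y; rec_w(b, col) = w;
        rec_alive(b, col) = 1;
      }
      if (ends) { out = (x >= m.xC[y]) ? 0 : 3; break; }

      int k = (int)std::llround(x / m.dx);
      if (k < 0) k = 0; if (k > m.nf - 1) k = m.nf - 1;
      int pod = t % m.ppd;
      bool is_day = pod >= m.d_start && pod < m.d_end;
      int i = policy[(R_xlen_t)S * t + k + m.nf * (y + m.ny * w)];
      int yn = next_y(m, i, y);
      if (col >= 0) rec_beh(b, col) = i;

      if (rng.u() < hazard_at(m, i, x, yn, is_day)) { out = 1; break; }

      double cost, sur;
      cost_of(m, i, x, yn, cost, sur);
      double gain = 0.0;
      if (i <= 2) {
        double lam = m.lambda[i - 1];
        bool succ = (lam >= 1.0) || (rng.u() < lam);
        gain = succ ? m.Gp[i - 1] : m.Gp[i - 1] * m.delta_;
      }
      double p_stay = (w == 0) ? m.pGG : m.pBB;
      int wn = (rng.u() < p_stay) ? w : 1 - w;
      double gfac = (wn == 1) ? m.gamma_ : 1.0;
      double xn = x + gain - cost * gfac - sur;
      if (xn > m.Xmax) xn = m.Xmax;
      ++t;
      if (xn <= 0.0) { out = 2; break; }
      x = xn; y = yn; w = wn;
    }
    outcome[b] = out;
    end_t[b] = t;
  }

  return List::create(_["outcome"] = outcome, _["end_period"] = end_t,
                      _["fat"] = rec_fat, _["y"] = rec_y,
                      _["behaviour"] = rec_beh, _["weather"] = rec_w,
                      _["alive"] = rec_alive);
}
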
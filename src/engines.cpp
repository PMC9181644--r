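// Monte Carlo survival engines.
//
// Damage model: DSB land in chromatin domains; a domain with one DSB is an
// isolated damage (iDSB), with two or more a clustered damage (cDSB).
// Timed engines deposit partial doses at the start of each of N_t equal
// sub-intervals and advance exponential repair between deposits. A DSB
// joining an isolated damage upgrades it (lifetime redrawn from the
// clustered distribution); every completed repair may fail (misrepair)
// with the class-specific lethality probability, which zeroes the
// iteration's survival. Survival of a clean iteration is
// (1-Ki)^n_i (1-Kc)^n_c over the damage left at the end of irradiation.
//
// All randomness flows through R's RNG so set.seed() governs every engine.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

constexpr double LN2 = 0.6931471805599453;

// Per-iteration damage bookkeeping over an arbitrary domain set.
struct DamageBook {
  int n_dom;
  std::vector<int> count;       // DSB count per domain
  std::vector<int> dom;         // domain of each active DSB
  std::vector<double> expiry;   // absolute repair time of each active DSB
  std::vector<int> touched;     // domains with nonzero count (for reset)
  std::vector<int> rem;         // scratch: indices expiring this pass
  int n_i = 0, n_c = 0;
  bool flag = false;            // misrepair occurred
  double sc_i, sc_c;            // exponential scales (mean lifetimes)
  double k_i, k_c;

  DamageBook(int n, double thalf_i, double thalf_c, double ki, double kc)
      : n_dom(n), count(n, 0), sc_i(thalf_i / LN2), sc_c(thalf_c / LN2),
        k_i(ki), k_c(kc) {}

  void reset() {
    for (int d : touched) count[d] = 0;
    touched.clear();
    dom.clear();
    expiry.clear();
    n_i = 0;
    n_c = 0;
    flag = false;
  }

  // deposit one DSB into domain d at time t
  void deposit(int d, double t) {
    int pre = count[d];
    if (pre == 0) {
      touched.push_back(d);
      dom.push_back(d);
      expiry.push_back(t + R::rexp(sc_i));
      ++n_i;
    } else {
      if (pre == 1) {
        // upgrade: redraw the resident isolated DSB's lifetime
        for (size_t j = 0; j < dom.size(); ++j)
          if (dom[j] == d) {
            expiry[j] = t + R::rexp(sc_c);
            break;
          }
        --n_i;
        ++n_c;
      }
      dom.push_back(d);
      expiry.push_back(t + R::rexp(sc_c));
    }
    count[d] = pre + 1;
  }

  // repair everything expiring by t_end; classification for the misrepair
  // draw is taken before any removal of this pass
  void advance(double t_end) {
    size_t n = dom.size();
    if (n == 0) return;
    rem.clear();
    for (size_t j = 0; j < n; ++j) {
      if (expiry[j] <= t_end) {
        double k = (count[dom[j]] >= 2) ? k_c : k_i;
        if (unif_rand() < k) flag = true;
        rem.push_back((int)j);
      }
    }
    // swap-remove from the back so earlier indices stay valid
    for (auto it = rem.rbegin(); it != rem.rend(); ++it) {
      int j = *it;
      int d = dom[j];
      int pre = count[d];
      if (pre == 1)
        --n_i;
      else if (pre == 2) {
        --n_c;
        ++n_i;
      }
      count[d] = pre - 1;
      dom[j] = dom.back();
      expiry[j] = expiry.back();
      dom.pop_back();
      expiry.pop_back();
    }
  }

  double survival() const {
    if (flag) return 0.0;
    return std::pow(1.0 - k_i, n_i) * std::pow(1.0 - k_c, n_c);
  }
};

}  // namespace

// Acute photon survival: Poisson total DSB, uniform allocation, no repair.
// [[Rcpp::export]]
NumericVector cpp_photon_acute(int n_iter, int n_domains, double mu_total,
                               double k_i, double k_c) {
  NumericVector out(n_iter);
  std::vector<int> count(n_domains, 0);
  std::vector<int> touched;
  for (int it = 0; it < n_iter; ++it) {
    for (int d : touched) count[d] = 0;
    touched.clear();
    int n_tot = (int)R::rpois(mu_total);
    for (int k = 0; k < n_tot; ++k) {
      int d = (int)(unif_rand() * n_domains);
      if (d >= n_domains) d = n_domains - 1;
      if (count[d] == 0) touched.push_back(d);
      ++count[d];
    }
    int ni = 0, nc = 0;
    for (int d : touched) {
      if (count[d] == 1)
        ++ni;
      else
        ++nc;
    }
    out[it] = std::pow(1.0 - k_i, ni) * std::pow(1.0 - k_c, nc);
  }
  return out;
}

// Timed photon survival: dose split into n_steps deposits at sub-interval
// starts, repair advanced between deposits.
// [[Rcpp::export]]
NumericVector cpp_photon_timed(int n_iter, int n_domains, double mu_total,
                               int n_steps, double dt, double k_i,
                               double k_c, double thalf_i, double thalf_c) {
  NumericVector out(n_iter);
  DamageBook book(n_domains, thalf_i, thalf_c, k_i, k_c);
  double mu_part = mu_total / n_steps;
  for (int it = 0; it < n_iter; ++it) {
    book.reset();
    for (int s = 0; s < n_steps; ++s) {
      double t = s * dt;
      int n_new = (int)R::rpois(mu_part);
      for (int k = 0; k < n_new; ++k) {
        int d = (int)(unif_rand() * n_domains);
        if (d >= n_domains) d = n_domains - 1;
        book.deposit(d, t);
      }
      book.advance(t + dt);
    }
    out[it] = book.survival();
  }
  return out;
}

// Exact expectation of the timed photon engine.
//
// Uniform allocation of Poisson-distributed DSB makes the domains iid:
// per tranche each domain receives Poisson(mu_dom_part) new DSB, and all
// repair/misrepair randomness is domain-local, so E[S] = f^N where f is
// the expected per-domain survival factor (misrepair-free paths weighted
// by their final classification factor). f follows a small state-space
// recursion over {empty, single(i-lifetime), single(c-lifetime), n >= 2}.
// [[Rcpp::export]]
double cpp_photon_timed_exact(int n_domains, double mu_dom_part,
                              int n_steps, double dt, double k_i,
                              double k_c, double thalf_i, double thalf_c,
                              int n_max = 40) {
  // Poisson arrival pmf, truncated where negligible
  std::vector<double> pois;
  {
    double p = std::exp(-mu_dom_part);
    int j = 0;
    while (j <= n_max) {
      pois.push_back(p);
      if (j > mu_dom_part && p < 1e-18) break;
      ++j;
      p *= mu_dom_part / j;
    }
  }
  int j_max = (int)pois.size() - 1;

  double q_i = 1.0 - std::exp(-LN2 * dt / thalf_i);
  double q_c = 1.0 - std::exp(-LN2 * dt / thalf_c);

  // binomial removal kernels for clustered states, indexed [n][m]
  std::vector<std::vector<double>> binom(n_max + 1);
  for (int n = 2; n <= n_max; ++n) {
    binom[n].resize(n + 1);
    double pm = std::pow(1.0 - q_c, n);  // m = 0
    double ratio = q_c / (1.0 - q_c);
    for (int m = 0; m <= n; ++m) {
      binom[n][m] = pm;
      pm *= ratio * (n - m) / (m + 1.0);
    }
  }

  // weights: w0, single with i/c lifetime, and clustered states
  double w0 = 1.0, w1i = 0.0, w1c = 0.0;
  std::vector<double> w(n_max + 1, 0.0), nw(n_max + 1, 0.0);

  for (int s = 0; s < n_steps; ++s) {
    // --- deposit tranche ---
    double v0 = 0.0, v1i = 0.0, v1c = 0.0;
    std::fill(nw.begin(), nw.end(), 0.0);
    // from empty
    v0 += w0 * pois[0];
    if (j_max >= 1) v1i += w0 * pois[1];
    for (int j = 2; j <= j_max; ++j) nw[std::min(j, n_max)] += w0 * pois[j];
    // from singles (any arrival clusters the domain; the resident DSB is
    // redrawn, which does not change the memoryless state)
    v1i += w1i * pois[0];
    v1c += w1c * pois[0];
    for (int j = 1; j <= j_max; ++j)
      nw[std::min(1 + j, n_max)] += (w1i + w1c) * pois[j];
    // from clustered
    for (int n = 2; n <= n_max; ++n) {
      if (w[n] == 0.0) continue;
      for (int j = 0; j <= j_max; ++j)
        nw[std::min(n + j, n_max)] += w[n] * pois[j];
    }
    w0 = v0;
    w1i = v1i;
    w1c = v1c;
    std::swap(w, nw);

    // --- repair over dt ---
    // singles are isolated at removal regardless of lifetime type
    w0 += w1i * q_i * (1.0 - k_i) + w1c * q_c * (1.0 - k_i);
    w1i *= (1.0 - q_i);
    w1c *= (1.0 - q_c);
    for (int n = n_max; n >= 2; --n) {
      if (w[n] == 0.0) continue;
      double base = w[n];
      w[n] = base * binom[n][0];
      for (int m = 1; m <= n; ++m) {
        double moved = base * binom[n][m] * std::pow(1.0 - k_c, m);
        int tgt = n - m;
        if (tgt == 0)
          w0 += moved;
        else if (tgt == 1)
          w1c += moved;  // declassified single keeps its clustered lifetime
        else
          w[tgt] += moved;
      }
    }
  }

  double f = w0 + (w1i + w1c) * (1.0 - k_i);
  for (int n = 2; n <= n_max; ++n) f += w[n] * (1.0 - k_c);
  return std::pow(f, (double)n_domains);
}

namespace {

// dose contribution of one track at squared distance d2 (three-step RDD)
inline double step_level(double d2, double r1sq, double r2sq, double r3sq,
                         double e1, double e2, double e3) {
  return d2 <= r1sq ? e1 : (d2 <= r2sq ? e2 : (d2 <= r3sq ? e3 : 0.0));
}

}  // namespace

// Acute ion survival. Tracks: Poisson count over the sampling disk,
// uniform positions; per-column yield-weighted dose by the midpoint rule;
// per-domain Poisson DSB; survival by the damage-classification law.
// [[Rcpp::export]]
NumericVector cpp_ion_acute(int n_iter, NumericVector col_x,
                            NumericVector col_y, int n_z,
                            double lambda_tracks, double r_samp,
                            NumericVector r_bounds, NumericVector lvl_eff,
                            double alpha_over_n, double k_i, double k_c) {
  int n_col = col_x.size();
  const double *cx = col_x.begin(), *cy = col_y.begin();
  double r1sq = r_bounds[0] * r_bounds[0];
  double r2sq = r_bounds[1] * r_bounds[1];
  double r3sq = r_bounds[2] * r_bounds[2];
  double e1 = lvl_eff[0], e2 = lvl_eff[1], e3 = lvl_eff[2];
  NumericVector out(n_iter);
  std::vector<double> coldose(n_col);
  std::vector<int> zcnt(n_z);

  for (int it = 0; it < n_iter; ++it) {
    std::fill(coldose.begin(), coldose.end(), 0.0);
    int m_tracks = (int)R::rpois(lambda_tracks);
    for (int m = 0; m < m_tracks; ++m) {
      double r = r_samp * std::sqrt(unif_rand());
      double th = 2.0 * M_PI * unif_rand();
      double x = r * std::cos(th), y = r * std::sin(th);
      for (int c = 0; c < n_col; ++c) {
        double dx = x - cx[c], dy = y - cy[c];
        double d2 = dx * dx + dy * dy;
        if (d2 <= r3sq)
          coldose[c] += d2 <= r1sq ? e1 : (d2 <= r2sq ? e2 : e3);
      }
    }
    int ni = 0, nc = 0;
    for (int c = 0; c < n_col; ++c) {
      if (coldose[c] <= 0.0) continue;
      double lam_dom = alpha_over_n * coldose[c];
      int n_col_dsb = (int)R::rpois(n_z * lam_dom);
      if (n_col_dsb == 0) continue;
      if (n_col_dsb == 1) {
        ++ni;
        continue;
      }
      std::fill(zcnt.begin(), zcnt.end(), 0);
      for (int k = 0; k < n_col_dsb; ++k) {
        int z = (int)(unif_rand() * n_z);
        if (z >= n_z) z = n_z - 1;
        ++zcnt[z];
      }
      for (int z = 0; z < n_z; ++z) {
        if (zcnt[z] == 1)
          ++ni;
        else if (zcnt[z] >= 2)
          ++nc;
      }
    }
    out[it] = std::pow(1.0 - k_i, ni) * std::pow(1.0 - k_c, nc);
  }
  return out;
}

// Timed ion survival: per tranche, fresh Poisson tracks for the partial
// dose are deposited and repair is advanced, sharing the photon engine's
// damage bookkeeping. Domains are indexed column-major: id = c*n_z + z.
// [[Rcpp::export]]
NumericVector cpp_ion_timed(int n_iter, NumericVector col_x,
                            NumericVector col_y, int n_z,
                            double lambda_tracks, double r_samp,
                            NumericVector r_bounds, NumericVector lvl_eff,
                            double alpha_over_n, int n_steps, double dt,
                            double k_i, double k_c, double thalf_i,
                            double thalf_c) {
  int n_col = col_x.size();
  const double *cx = col_x.begin(), *cy = col_y.begin();
  double r1sq = r_bounds[0] * r_bounds[0];
  double r2sq = r_bounds[1] * r_bounds[1];
  double r3sq = r_bounds[2] * r_bounds[2];
  double e1 = lvl_eff[0], e2 = lvl_eff[1], e3 = lvl_eff[2];
  double lam_part = lambda_tracks / n_steps;
  NumericVector out(n_iter);
  std::vector<double> coldose(n_col);
  DamageBook book(n_col * n_z, thalf_i, thalf_c, k_i, k_c);

  for (int it = 0; it < n_iter; ++it) {
    book.reset();
    for (int s = 0; s < n_steps; ++s) {
      double t = s * dt;
      std::fill(coldose.begin(), coldose.end(), 0.0);
      int m_tracks = (int)R::rpois(lam_part);
      for (int m = 0; m < m_tracks; ++m) {
        double r = r_samp * std::sqrt(unif_rand());
        double th = 2.0 * M_PI * unif_rand();
        double x = r * std::cos(th), y = r * std::sin(th);
        for (int c = 0; c < n_col; ++c) {
          double dx = x - cx[c], dy = y - cy[c];
          double d2 = dx * dx + dy * dy;
          if (d2 <= r3sq)
            coldose[c] += d2 <= r1sq ? e1 : (d2 <= r2sq ? e2 : e3);
        }
      }
      for (int c = 0; c < n_col; ++c) {
        if (coldose[c] <= 0.0) continue;
        int n_col_dsb = (int)R::rpois(n_z * alpha_over_n * coldose[c]);
        for (int k = 0; k < n_col_dsb; ++k) {
          int z = (int)(unif_rand() * n_z);
          if (z >= n_z) z = n_z - 1;
          book.deposit(c * n_z + z, t);
        }
      }
      book.advance(t + dt);
    }
    out[it] = book.survival();
  }
  return out;
}
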
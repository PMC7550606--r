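// Metropolis-within-Gibbs sampler for the two-state switching
// first-difference correlated random walk (DCRW) state-space model with
// t-distributed Argos observation errors.
//
// Latent per segment: regular-grid locations x_t (lon/lat degrees) and
// behavioural states b_t in {0 = transit, 1 = ARS}. Process model
//   d_t = gamma_b T(theta_b) d_{t-1} + eta_t,  d_t = x_t - x_{t-1},
// eta_t ~ N2(0, diag(sigma_lon^2, sigma_lat^2)). Observations interpolate
// linearly between bracketing grid locations and carry fixed per-class
// t error scales/df. Movement parameters are pooled across all segments
// (hierarchical population-level parameters); states are sampled exactly
// by forward-filtering backward-sampling, locations and movement
// parameters by adaptive random-walk Metropolis, and the transition
// matrix by its conjugate Beta/Dirichlet update.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Par {
  double g[2];            // persistence per state
  double th[2];           // turning angle per state
  double c[2], s[2];      // cos/sin of th
  double sx, sy;          // process noise SD per coordinate
  double A[2][2];         // row-stochastic transition matrix
  void set_theta(int k, double v) { th[k] = v; c[k] = std::cos(v); s[k] = std::sin(v); }
};

struct Seg {
  int T;
  std::vector<double> x, y;           // latent path
  std::vector<double> oy1, oy2;       // observed lon/lat
  std::vector<int> idxL;              // 0-based left bracket per obs
  std::vector<double> frac, scale, df;
  std::vector<std::vector<int> > obs_in; // obs ids per grid interval
  std::vector<int> b;                 // state per grid point
  double prop_x;                      // RW proposal SD for locations
};

inline double tkern(double e, double scale, double df) {
  return -0.5 * (df + 1.0) * std::log1p(e * e / (df * scale * scale));
}

// Gaussian process log-density of displacement t (t >= 2), state forced
inline double proc_term_state(const Seg& S, int t, const Par& P, int k) {
  double dxp = S.x[t - 1] - S.x[t - 2], dyp = S.y[t - 1] - S.y[t - 2];
  double dx = S.x[t] - S.x[t - 1],     dy = S.y[t] - S.y[t - 1];
  double mx = P.g[k] * (P.c[k] * dxp - P.s[k] * dyp);
  double my = P.g[k] * (P.s[k] * dxp + P.c[k] * dyp);
  double ex = (dx - mx) / P.sx, ey = (dy - my) / P.sy;
  return -0.5 * (ex * ex + ey * ey) - std::log(P.sx) - std::log(P.sy);
}

inline double proc_term(const Seg& S, int t, const Par& P) {
  return proc_term_state(S, t, P, S.b[t]);
}

// all terms touched by x_t / y_t
double loc_ll(const Seg& S, int t, const Par& P) {
  double ll = 0.0;
  int lo = std::max(2, t), hi = std::min(t + 2, S.T - 1);
  for (int s = lo; s <= hi; ++s) ll += proc_term(S, s, P);
  for (int itv = t - 1; itv <= t; ++itv) {
    if (itv < 0 || itv > S.T - 2) continue;
    const std::vector<int>& ids = S.obs_in[itv];
    for (size_t q = 0; q < ids.size(); ++q) {
      int oi = ids[q];
      double w = S.frac[oi];
      double px = (1.0 - w) * S.x[itv] + w * S.x[itv + 1];
      double py = (1.0 - w) * S.y[itv] + w * S.y[itv + 1];
      ll += tkern(S.oy1[oi] - px, S.scale[oi], S.df[oi]);
      ll += tkern(S.oy2[oi] - py, S.scale[oi], S.df[oi]);
    }
  }
  return ll;
}

// total process log-likelihood, optionally restricted to one state
double proc_ll_all(const std::vector<Seg>& segs, const Par& P,
                   int only_state = -1) {
  double ll = 0.0;
  for (size_t i = 0; i < segs.size(); ++i) {
    const Seg& S = segs[i];
    for (int t = 2; t < S.T; ++t) {
      if (only_state >= 0 && S.b[t] != only_state) continue;
      ll += proc_term(S, t, P);
    }
  }
  return ll;
}

void ffbs(Seg& S, const Par& P) {
  int T = S.T;
  std::vector<double> a0(T), a1(T);    // forward log-probs
  double lA[2][2];
  for (int i = 0; i < 2; ++i)
    for (int j = 0; j < 2; ++j) lA[i][j] = std::log(P.A[i][j]);
  a0[0] = std::log(0.5); a1[0] = std::log(0.5);
  for (int t = 1; t < T; ++t) {
    double e0 = (t >= 2) ? proc_term_state(S, t, P, 0) : 0.0;
    double e1 = (t >= 2) ? proc_term_state(S, t, P, 1) : 0.0;
    double m0 = std::max(a0[t - 1] + lA[0][0], a1[t - 1] + lA[1][0]);
    double m1 = std::max(a0[t - 1] + lA[0][1], a1[t - 1] + lA[1][1]);
    a0[t] = m0 + std::log(std::exp(a0[t - 1] + lA[0][0] - m0) +
                          std::exp(a1[t - 1] + lA[1][0] - m0)) + e0;
    a1[t] = m1 + std::log(std::exp(a0[t - 1] + lA[0][1] - m1) +
                          std::exp(a1[t - 1] + lA[1][1] - m1)) + e1;
  }
  double m = std::max(a0[T - 1], a1[T - 1]);
  double p1 = std::exp(a1[T - 1] - m) /
    (std::exp(a0[T - 1] - m) + std::exp(a1[T - 1] - m));
  S.b[T - 1] = (unif_rand() < p1) ? 1 : 0;
  for (int t = T - 2; t >= 0; --t) {
    int k = S.b[t + 1];
    double w0 = a0[t] + lA[0][k], w1 = a1[t] + lA[1][k];
    double mm = std::max(w0, w1);
    double q1 = std::exp(w1 - mm) / (std::exp(w0 - mm) + std::exp(w1 - mm));
    S.b[t] = (unif_rand() < q1) ? 1 : 0;
  }
}

} // namespace

// [[Rcpp::export]]
List run_dcrw_chain(List seg_data, List init, List priors,
                    int n_iter, int n_burn, int thin) {
  int nseg = seg_data.size();
  std::vector<Seg> segs(nseg);
  for (int i = 0; i < nseg; ++i) {
    List sd = seg_data[i];
    Seg& S = segs[i];
    NumericVector xi = sd["x"], yi = sd["y"];
    S.T = xi.size();
    S.x.assign(xi.begin(), xi.end());
    S.y.assign(yi.begin(), yi.end());
    NumericVector o1 = sd["obs_lon"], o2 = sd["obs_lat"],
      fr = sd["frac"], sc = sd["scale"], df = sd["df"];
    IntegerVector il = sd["idxL"];
    S.oy1.assign(o1.begin(), o1.end());
    S.oy2.assign(o2.begin(), o2.end());
    S.frac.assign(fr.begin(), fr.end());
    S.scale.assign(sc.begin(), sc.end());
    S.df.assign(df.begin(), df.end());
    S.idxL.assign(il.begin(), il.end());
    S.obs_in.assign(std::max(S.T - 1, 1), std::vector<int>());
    for (size_t o = 0; o < S.idxL.size(); ++o) {
      int l = S.idxL[o];
      if (l >= 0 && l <= S.T - 2) S.obs_in[l].push_back((int)o);
    }
    IntegerVector bi = sd["b"];
    S.b.assign(bi.begin(), bi.end());
    S.prop_x = as<double>(sd["prop_x"]);
  }

  Par P;
  NumericVector g0 = init["gamma"], th0 = init["theta"], sg0 = init["sigma"];
  P.g[0] = g0[0]; P.g[1] = g0[1];
  P.set_theta(0, th0[0]); P.set_theta(1, th0[1]);
  P.sx = sg0[0]; P.sy = sg0[1];
  NumericMatrix A0 = init["switch_probs"];
  for (int i = 0; i < 2; ++i)
    for (int j = 0; j < 2; ++j) P.A[i][j] = A0(i, j);

  double ga = as<double>(priors["gamma_shape1"]);
  double gb = as<double>(priors["gamma_shape2"]);
  double sig_scale = as<double>(priors["sigma_scale"]);
  double dir_a = as<double>(priors["dirichlet_alpha"]);

  // adaptive RW proposal scales: gamma (logit), theta, log sigma
  double prop_g[2] = {0.3, 0.3}, prop_t[2] = {0.3, 0.3},
    prop_s[2] = {0.2, 0.2};
  long acc_g[2] = {0, 0}, try_g[2] = {0, 0};
  long acc_t[2] = {0, 0}, try_t[2] = {0, 0};
  long acc_s[2] = {0, 0}, try_s[2] = {0, 0};
  std::vector<long> acc_x(nseg, 0), try_x(nseg, 0);

  int n_ret = (n_iter - n_burn) / thin;
  NumericMatrix draws(n_ret, 8);
  colnames(draws) = CharacterVector::create(
    "gamma_transit", "gamma_ars", "theta_transit", "theta_ars",
    "sigma_lon", "sigma_lat", "p_stay_transit", "p_stay_ars");
  std::vector<std::vector<double> > xs(nseg), ys(nseg);
  std::vector<std::vector<long> > b2(nseg);
  for (int i = 0; i < nseg; ++i) {
    xs[i].assign(segs[i].T, 0.0);
    ys[i].assign(segs[i].T, 0.0);
    b2[i].assign(segs[i].T, 0L);
  }

  GetRNGstate();
  for (int iter = 1; iter <= n_iter; ++iter) {
    // 1. latent locations, single-site RW Metropolis
    for (int i = 0; i < nseg; ++i) {
      Seg& S = segs[i];
      for (int t = 0; t < S.T; ++t) {
        double ox = S.x[t], oy = S.y[t];
        double ll0 = loc_ll(S, t, P);
        S.x[t] = ox + norm_rand() * S.prop_x;
        S.y[t] = oy + norm_rand() * S.prop_x;
        double ll1 = loc_ll(S, t, P);
        ++try_x[i];
        if (std::log(unif_rand()) < ll1 - ll0) ++acc_x[i];
        else { S.x[t] = ox; S.y[t] = oy; }
      }
    }

    // 2. behavioural states by FFBS
    for (int i = 0; i < nseg; ++i) ffbs(segs[i], P);

    // 3. transition matrix, conjugate Beta update from pooled counts
    double n00 = 0, n01 = 0, n10 = 0, n11 = 0;
    for (int i = 0; i < nseg; ++i) {
      const Seg& S = segs[i];
      for (int t = 1; t < S.T; ++t) {
        int a = S.b[t - 1], b = S.b[t];
        if (a == 0 && b == 0) ++n00;
        else if (a == 0 && b == 1) ++n01;
        else if (a == 1 && b == 0) ++n10;
        else ++n11;
      }
    }
    double a00 = R::rbeta(dir_a + n00, dir_a + n01);
    double a11 = R::rbeta(dir_a + n11, dir_a + n10);
    P.A[0][0] = a00; P.A[0][1] = 1.0 - a00;
    P.A[1][1] = a11; P.A[1][0] = 1.0 - a11;

    // 4. movement parameters, RW Metropolis on transformed scales
    for (int k = 0; k < 2; ++k) { // gamma_k on logit scale
      double g = P.g[k];
      double lo = std::log(g / (1.0 - g)) + norm_rand() * prop_g[k];
      double gn = 1.0 / (1.0 + std::exp(-lo));
      double ll0 = proc_ll_all(segs, P, k) +
        (ga - 1) * std::log(g) + (gb - 1) * std::log(1 - g) +
        std::log(g) + std::log(1 - g); // Jacobian of logit
      Par Q = P; Q.g[k] = gn;
      double ll1 = proc_ll_all(segs, Q, k) +
        (ga - 1) * std::log(gn) + (gb - 1) * std::log(1 - gn) +
        std::log(gn) + std::log(1 - gn);
      ++try_g[k];
      if (std::log(unif_rand()) < ll1 - ll0) { P.g[k] = gn; ++acc_g[k]; }
    }
    for (int k = 0; k < 2; ++k) { // theta_k, wrapped uniform prior
      double tn = P.th[k] + norm_rand() * prop_t[k];
      tn = std::atan2(std::sin(tn), std::cos(tn)); // wrap to (-pi, pi]
      double ll0 = proc_ll_all(segs, P, k);
      Par Q = P; Q.set_theta(k, tn);
      double ll1 = proc_ll_all(segs, Q, k);
      ++try_t[k];
      if (std::log(unif_rand()) < ll1 - ll0) { P.set_theta(k, tn); ++acc_t[k]; }
    }
    for (int k = 0; k < 2; ++k) { // log sigma, half-normal prior
      double cur = (k == 0) ? P.sx : P.sy;
      double sn = cur * std::exp(norm_rand() * prop_s[k]);
      if (sn < 1e-6) sn = 1e-6;
      double ll0 = proc_ll_all(segs, P) -
        cur * cur / (2 * sig_scale * sig_scale) + std::log(cur);
      Par Q = P; if (k == 0) Q.sx = sn; else Q.sy = sn;
      double ll1 = proc_ll_all(segs, Q) -
        sn * sn / (2 * sig_scale * sig_scale) + std::log(sn);
      ++try_s[k];
      if (std::log(unif_rand()) < ll1 - ll0) {
        if (k == 0) P.sx = sn; else P.sy = sn;
        ++acc_s[k];
      }
    }

    // 5. identifiability: state 0 is the persistent (transit) state
    if (P.g[0] < P.g[1]) {
      std::swap(P.g[0], P.g[1]);
      double t0 = P.th[0], t1 = P.th[1];
      P.set_theta(0, t1); P.set_theta(1, t0);
      double B[2][2];
      for (int i = 0; i < 2; ++i)
        for (int j = 0; j < 2; ++j) B[i][j] = P.A[1 - i][1 - j];
      for (int i = 0; i < 2; ++i)
        for (int j = 0; j < 2; ++j) P.A[i][j] = B[i][j];
      for (int i = 0; i < nseg; ++i)
        for (int t = 0; t < segs[i].T; ++t) segs[i].b[t] = 1 - segs[i].b[t];
    }

    // adapt proposals during burn-in
    if (iter <= n_burn && iter % 50 == 0) {
      for (int k = 0; k < 2; ++k) {
        if (try_g[k]) prop_g[k] *= std::exp(((double)acc_g[k] / try_g[k] - 0.3));
        if (try_t[k]) prop_t[k] *= std::exp(((double)acc_t[k] / try_t[k] - 0.3));
        if (try_s[k]) prop_s[k] *= std::exp(((double)acc_s[k] / try_s[k] - 0.3));
        acc_g[k] = try_g[k] = acc_t[k] = try_t[k] = acc_s[k] = try_s[k] = 0;
      }
      for (int i = 0; i < nseg; ++i) {
        if (try_x[i]) {
          segs[i].prop_x *=
            std::exp(((double)acc_x[i] / try_x[i] - 0.3) * 0.5);
          segs[i].prop_x = std::max(segs[i].prop_x, 1e-6);
          acc_x[i] = try_x[i] = 0;
        }
        prop_g[0] = std::min(std::max(prop_g[0], 1e-3), 5.0);
      }
    }

    // retain
    if (iter > n_burn && (iter - n_burn) % thin == 0) {
      int r = (iter - n_burn) / thin - 1;
      if (r < n_ret) {
        draws(r, 0) = P.g[0]; draws(r, 1) = P.g[1];
        draws(r, 2) = P.th[0]; draws(r, 3) = P.th[1];
        draws(r, 4) = P.sx; draws(r, 5) = P.sy;
        draws(r, 6) = P.A[0][0]; draws(r, 7) = P.A[1][1];
        for (int i = 0; i < nseg; ++i) {
          for (int t = 0; t < segs[i].T; ++t) {
            xs[i][t] += segs[i].x[t];
            ys[i][t] += segs[i].y[t];
            if (segs[i].b[t] == 1) ++b2[i][t];
          }
        }
      }
    }
    if (iter % 512 == 0) Rcpp::checkUserInterrupt();
  }
  PutRNGstate();

  List seg_out(nseg);
  for (int i = 0; i < nseg; ++i) {
    int T = segs[i].T;
    NumericVector mx(T), my(T), bm(T);
    for (int t = 0; t < T; ++t) {
      mx[t] = xs[i][t] / n_ret;
      my[t] = ys[i][t] / n_ret;
      bm[t] = 1.0 + (double)b2[i][t] / n_ret; // mean of samples in {1,2}
    }
    seg_out[i] = List::create(_["lon"] = mx, _["lat"] = my,
                              _["b_mean"] = bm);
  }
  double xacc = 0, xtry = 0;
  for (int i = 0; i < nseg; ++i) { xacc += acc_x[i]; xtry += try_x[i]; }
  return List::create(
    _["draws"] = draws,
    _["segments"] = seg_out,
    _["accept_x"] = xtry > 0 ? xacc / xtry : NA_REAL);
}
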
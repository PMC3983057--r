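// Metropolis-within-Gibbs sampler for a two-state switching first-difference
// correlated random walk observed through irregular fixes with known,
// class-specific Gaussian error, on a planar local projection (km).
//
// States: 1 = transient (high persistence gamma1), 2 = resident (gamma2),
// identified by restricting gamma1 to (gamma_split, 1] and gamma2 to
// [0, gamma_split), which removes label switching. The state s_t
// governs difference d_t = x_{t+1} - x_t for t = 1..T-1; d_1 is diffuse.
// Position updates are random-walk Metropolis (adapted during burn-in);
// states, persistence parameters, process variance and the transition
// matrix have conjugate Gibbs updates.

#include <Rcpp.h>
using namespace Rcpp;

static inline double rtruncnorm01(double mean, double sd, double lo,
                                  double hi) {
  // inverse-CDF truncated normal on [lo, hi]; degenerate tails fall back
  // to uniform on the interval.
  double plo = R::pnorm(lo, mean, sd, 1, 0);
  double phi = R::pnorm(hi, mean, sd, 1, 0);
  if (phi - plo < 1e-12) {
    return R::runif(lo, hi);
  }
  double u = R::runif(plo, phi);
  double x = R::qnorm(u, mean, sd, 1, 0);
  if (x < lo) x = lo;
  if (x > hi) x = hi;
  return x;
}

// [[Rcpp::export]]
List sssm_mcmc(NumericMatrix y, NumericVector obs_sd, IntegerVector bidx,
               NumericVector w, int T, NumericMatrix x_init,
               int n_iter, int n_burn, int thin,
               double d1_sd, double prop_sd_init,
               double prior_a0, double prior_b0, double gamma_split) {
  RNGScope scope;
  const int n = y.nrow();

  // fixes touching each block (bidx is 0-based left block of the fix)
  std::vector< std::vector<int> > touch(T);
  for (int i = 0; i < n; ++i) {
    int k = bidx[i];
    touch[k].push_back(i);
    if (k + 1 < T) touch[k + 1].push_back(i);
  }

  NumericMatrix x = clone(x_init);
  std::vector<int> s(T - 1, 0);            // 0 = transient, 1 = resident
  double gamma[2] = {0.7, 0.2};
  double sig2 = 4.0;
  double A[2][2] = {{0.9, 0.1}, {0.1, 0.9}};

  // crude initial states from step lengths
  {
    double tot = 0;
    std::vector<double> len(T - 1);
    for (int t = 0; t < T - 1; ++t) {
      double dx = x(t + 1, 0) - x(t, 0), dy = x(t + 1, 1) - x(t, 1);
      len[t] = std::sqrt(dx * dx + dy * dy);
      tot += len[t];
    }
    double mean_len = tot / (T - 1);
    for (int t = 0; t < T - 1; ++t) s[t] = (len[t] < 0.7 * mean_len) ? 1 : 0;
  }

  std::vector<double> prop_sd(T, prop_sd_init), acc(T, 0.0), tries(T, 0.0);

  // observation log-likelihood contribution of fix i given current x
  auto obs_ll = [&](int i) {
    int k = bidx[i];
    double wx = w[i];
    double mx = (1 - wx) * x(k, 0) + (k + 1 < T ? wx * x(k + 1, 0) : 0.0);
    double my = (1 - wx) * x(k, 1) + (k + 1 < T ? wx * x(k + 1, 1) : 0.0);
    double rx = y(i, 0) - mx, ry = y(i, 1) - my;
    double v = obs_sd[i] * obs_sd[i];
    return -0.5 * (rx * rx + ry * ry) / v;
  };

  // process log-density of difference t (1-based t in 1..T-1; index t-1)
  auto proc_ll = [&](int t) {
    if (t < 1 || t > T - 1) return 0.0;
    double dx = x(t, 0) - x(t - 1, 0), dy = x(t, 1) - x(t - 1, 1);
    if (t == 1) {
      double v = d1_sd * d1_sd;
      return -0.5 * (dx * dx + dy * dy) / v - std::log(v);
    }
    double g = gamma[s[t - 1]];
    double px = x(t - 1, 0) - x(t - 2, 0), py = x(t - 1, 1) - x(t - 2, 1);
    double rx = dx - g * px, ry = dy - g * py;
    return -0.5 * (rx * rx + ry * ry) / sig2 - std::log(sig2);
  };

  int n_kept = 0;
  NumericMatrix x_sum(T, 2), x_sum2(T, 2);
  NumericVector state1_cnt(T - 1);
  std::vector<double> g1s, g2s, sigs, a11s, a22s;

  for (int iter = 0; iter < n_iter; ++iter) {
    // --- positions: random-walk Metropolis, one block at a time
    for (int k = 0; k < T; ++k) {
      double oldx = x(k, 0), oldy = x(k, 1);
      double cur = proc_ll(k) + proc_ll(k + 1) + proc_ll(k + 2);
      for (size_t j = 0; j < touch[k].size(); ++j)
        cur += obs_ll(touch[k][j]);
      x(k, 0) = oldx + R::norm_rand() * prop_sd[k];
      x(k, 1) = oldy + R::norm_rand() * prop_sd[k];
      double prop = proc_ll(k) + proc_ll(k + 1) + proc_ll(k + 2);
      for (size_t j = 0; j < touch[k].size(); ++j)
        prop += obs_ll(touch[k][j]);
      tries[k] += 1;
      if (std::log(R::unif_rand()) < prop - cur) {
        acc[k] += 1;
      } else {
        x(k, 0) = oldx;
        x(k, 1) = oldy;
      }
    }
    if (iter < n_burn && (iter + 1) % 50 == 0) {
      for (int k = 0; k < T; ++k) {
        if (tries[k] > 0) {
          double rate = acc[k] / tries[k];
          prop_sd[k] *= std::exp(0.3 * (rate - 0.35));
          if (prop_sd[k] < 1e-4) prop_sd[k] = 1e-4;
          acc[k] = 0;
          tries[k] = 0;
        }
      }
    }

    // --- states: Gibbs (s_1 has no process term; d_1 is diffuse)
    for (int t = 1; t <= T - 1; ++t) {
      int ti = t - 1;
      double logp[2];
      for (int j = 0; j < 2; ++j) {
        double lp = 0.0;
        if (ti > 0) lp += std::log(A[s[ti - 1]][j]);
        else lp += std::log(A[1][0] + A[0][1] > 0
                              ? (j == 0 ? A[1][0] : A[0][1]) /
                                  (A[1][0] + A[0][1])
                              : 0.5);
        if (ti + 1 < T - 1) lp += std::log(A[j][s[ti + 1]]);
        if (t >= 2) {
          double dx = x(t, 0) - x(t - 1, 0), dy = x(t, 1) - x(t - 1, 1);
          double px = x(t - 1, 0) - x(t - 2, 0),
                 py = x(t - 1, 1) - x(t - 2, 1);
          double rx = dx - gamma[j] * px, ry = dy - gamma[j] * py;
          lp += -0.5 * (rx * rx + ry * ry) / sig2;
        }
        logp[j] = lp;
      }
      double m = std::max(logp[0], logp[1]);
      double p0 = std::exp(logp[0] - m);
      double p1 = std::exp(logp[1] - m);
      s[ti] = (R::unif_rand() < p0 / (p0 + p1)) ? 0 : 1;
    }

    // --- persistence parameters: truncated-normal Gibbs with ordering
    for (int j = 0; j < 2; ++j) {
      double sxy = 0, sxx = 0;
      for (int t = 2; t <= T - 1; ++t) {
        if (s[t - 1] != j) continue;
        double dx = x(t, 0) - x(t - 1, 0), dy = x(t, 1) - x(t - 1, 1);
        double px = x(t - 1, 0) - x(t - 2, 0),
               py = x(t - 1, 1) - x(t - 2, 1);
        sxy += dx * px + dy * py;
        sxx += px * px + py * py;
      }
      // identifiability: transient persistence lives above the split,
      // resident below it
      double lo = (j == 0) ? gamma_split : 0.0;
      double hi = (j == 0) ? 1.0 : gamma_split;
      if (sxx > 0) {
        gamma[j] = rtruncnorm01(sxy / sxx, std::sqrt(sig2 / sxx), lo, hi);
      } else {
        gamma[j] = R::runif(lo, hi);
      }
    }

    // --- process variance: inverse-gamma Gibbs
    {
      double ss = 0;
      int m = 0;
      for (int t = 2; t <= T - 1; ++t) {
        double g = gamma[s[t - 1]];
        double dx = x(t, 0) - x(t - 1, 0), dy = x(t, 1) - x(t - 1, 1);
        double px = x(t - 1, 0) - x(t - 2, 0),
               py = x(t - 1, 1) - x(t - 2, 1);
        double rx = dx - g * px, ry = dy - g * py;
        ss += rx * rx + ry * ry;
        m += 2;
      }
      sig2 = 1.0 / R::rgamma(prior_a0 + 0.5 * m,
                             1.0 / (prior_b0 + 0.5 * ss));
    }

    // --- transition matrix rows: Beta Gibbs
    {
      int n00 = 0, n01 = 0, n10 = 0, n11 = 0;
      for (int t = 0; t + 1 < T - 1; ++t) {
        if (s[t] == 0 && s[t + 1] == 0) n00++;
        else if (s[t] == 0) n01++;
        else if (s[t + 1] == 0) n10++;
        else n11++;
      }
      double a = R::rbeta(1.0 + n00, 1.0 + n01);
      double b = R::rbeta(1.0 + n11, 1.0 + n10);
      A[0][0] = a; A[0][1] = 1 - a;
      A[1][1] = b; A[1][0] = 1 - b;
    }

    // --- record
    if (iter >= n_burn && (iter - n_burn) % thin == 0) {
      ++n_kept;
      for (int k = 0; k < T; ++k) {
        x_sum(k, 0) += x(k, 0);
        x_sum(k, 1) += x(k, 1);
        x_sum2(k, 0) += x(k, 0) * x(k, 0);
        x_sum2(k, 1) += x(k, 1) * x(k, 1);
      }
      for (int t = 0; t < T - 1; ++t)
        if (s[t] == 0) state1_cnt[t] += 1;
      g1s.push_back(gamma[0]);
      g2s.push_back(gamma[1]);
      sigs.push_back(std::sqrt(sig2));
      a11s.push_back(A[0][0]);
      a22s.push_back(A[1][1]);
    }
  }

  NumericMatrix x_mean(T, 2), x_sd(T, 2);
  for (int k = 0; k < T; ++k) {
    for (int c = 0; c < 2; ++c) {
      double m = x_sum(k, c) / n_kept;
      x_mean(k, c) = m;
      double var = x_sum2(k, c) / n_kept - m * m;
      x_sd(k, c) = std::sqrt(var > 0 ? var : 0);
    }
  }
  NumericVector b(T - 1);
  for (int t = 0; t < T - 1; ++t) b[t] = 1.0 - state1_cnt[t] / n_kept;

  double acc_rate = 0;
  for (int k = 0; k < T; ++k)
    acc_rate += (tries[k] > 0 ? acc[k] / tries[k] : 0) / T;

  return List::create(_["x_mean"] = x_mean, _["x_sd"] = x_sd,
                      _["b"] = b, _["gamma1"] = wrap(g1s),
                      _["gamma2"] = wrap(g2s), _["sigma"] = wrap(sigs),
                      _["a11"] = wrap(a11s), _["a22"] = wrap(a22s),
                      _["n_kept"] = n_kept, _["accept"] = acc_rate);
}
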
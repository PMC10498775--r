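// Adaptive Metropolis-within-Gibbs sampler for one-parameter generalized
// logistic (Stukel-link) IRT models and the 3PL/4PL logistic models.
//
// Family codes:
//   0 = generalized logit link (lambda per item; optionally sampled)
//   1 = exact probit (normal ogive)
//   2 = exact complementary log-log
//   3 = 3PL/4PL logistic (alpha, c, d per item; d fixed at 1 for 3PL)
//
// All proposals are scalar random walks; step sizes are adapted toward a
// 0.44 acceptance rate in batches during burn-in and frozen afterwards, so
// the retained draws come from a fixed (valid) Markov kernel.  Uses R's RNG
// stream: results are reproducible via set.seed() on the R side.
//
// The per-cell log-likelihood cache is kept in both row-major (person
// updates scan a contiguous row) and column-major (item updates scan a
// contiguous column) layouts; accepted moves write both.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double LAMBDA_LIN = 1e-8;  // |lambda| below this: linear limit

static inline double h_glogit(double eta, double l1, double l2) {
  if (eta > 0.0) {
    if (l1 > LAMBDA_LIN)  return std::expm1(l1 * eta) / l1;
    if (l1 < -LAMBDA_LIN) return -std::log1p(-l1 * eta) / l1;
    return eta;
  }
  double a = -eta;  // eta <= 0 branch, mirrored with a sign flip
  if (l2 > LAMBDA_LIN)  return -std::expm1(l2 * a) / l2;
  if (l2 < -LAMBDA_LIN) return std::log1p(-l2 * a) / l2;
  return eta;
}

// Bernoulli log-likelihood under p = logistic(h), overflow-safe.
static inline double ll_logit(int x, double h) {
  if (h > 700.0) h = 700.0;
  else if (h < -700.0) h = -700.0;
  double lse = (h > 35.0) ? h + std::exp(-h) : std::log1p(std::exp(h));
  return x ? (h - lse) : (-lse);
}

static inline double cell_ll(int x, double theta, int fam, double beta,
                             double l1, double l2,
                             double alpha, double cpar, double dpar) {
  double eta = theta - beta;
  switch (fam) {
  case 0:
    return ll_logit(x, h_glogit(eta, l1, l2));
  case 1:
    return R::pnorm(x ? eta : -eta, 0.0, 1.0, 1, 1);
  case 2: {
    // p = 1 - exp(-exp(eta))
    double t = std::exp(std::min(eta, 700.0));
    if (!x) return -t;
    if (t < 1e-10) return std::min(eta, 700.0) - 0.5 * t;  // log p ~ eta
    if (t > 36.0) return 0.0;
    return std::log(-std::expm1(-t));
  }
  default: {
    double z = alpha * eta;
    double q = (z > 0.0) ? 1.0 / (1.0 + std::exp(-z))
                         : std::exp(z) / (1.0 + std::exp(z));
    double p = cpar + (dpar - cpar) * q;
    if (p < 1e-12) p = 1e-12;
    if (p > 1.0 - 1e-12) p = 1.0 - 1e-12;
    return x ? std::log(p) : std::log1p(-p);
  }
  }
}

struct Adapt {
  std::vector<double> step;
  std::vector<int> acc, tries;
  Adapt(int n, double s0) : step(n, s0), acc(n, 0), tries(n, 0) {}
  void update(int batch) {
    double gain = 1.0 / std::sqrt((double)batch);
    for (size_t k = 0; k < step.size(); ++k) {
      if (tries[k] == 0) continue;
      double rate = (double)acc[k] / (double)tries[k];
      step[k] *= std::exp(gain * (rate - 0.44));
      if (step[k] < 1e-3) step[k] = 1e-3;
      if (step[k] > 20.0) step[k] = 20.0;
      acc[k] = 0; tries[k] = 0;
    }
  }
};

// [[Rcpp::export(name = ".girt_chain")]]
List girt_chain(IntegerMatrix X, int family,
                bool sample_lambda, NumericVector lambda1_init,
                NumericVector lambda2_init, bool sample_d,
                int n_iter, int n_burnin,
                double sigma_beta_fixed,   // > 0: held fixed, not sampled
                int init_mode,             // 0 = prior draw, 1 = near zero
                bool store_loglik,
                int item_sweeps) {         // item-parameter sweeps per iteration
  const int N = X.nrow(), J = X.ncol();
  const int S = n_iter - n_burnin;
  const bool sample_sb = !(sigma_beta_fixed > 0.0);

  // current state ------------------------------------------------------
  std::vector<double> theta(N), beta(J), l1(J), l2(J);
  std::vector<double> alpha(J, 1.0), cpar(J, 0.0), dpar(J, 1.0);
  double sb = sample_sb ? 1.0 : sigma_beta_fixed, sl = 0.5;

  for (int j = 0; j < J; ++j) { l1[j] = lambda1_init[j]; l2[j] = lambda2_init[j]; }
  if (init_mode == 0) {
    for (int i = 0; i < N; ++i) theta[i] = norm_rand();
    for (int j = 0; j < J; ++j) beta[j] = sb * norm_rand();
  } else {
    for (int i = 0; i < N; ++i) theta[i] = 0.01 * norm_rand();
    for (int j = 0; j < J; ++j) beta[j] = 0.01 * norm_rand();
  }
  if (family == 3) {
    for (int j = 0; j < J; ++j) {
      alpha[j] = (init_mode == 0) ? std::exp(0.5 * norm_rand()) : 1.0;
      cpar[j] = (init_mode == 0) ? 0.5 * unif_rand() : 0.1;
      dpar[j] = sample_d ? ((init_mode == 0) ? 0.5 + 0.5 * unif_rand() : 0.9) : 1.0;
    }
  }

  // data + per-cell log-likelihood caches, both layouts ------------------
  std::vector<int> Xc((size_t)N * J), Xr((size_t)N * J);   // col-/row-major
  std::vector<char> obs_c((size_t)N * J), obs_r((size_t)N * J);
  bool has_missing = false;
  int M = 0;
  for (int j = 0; j < J; ++j)
    for (int i = 0; i < N; ++i) {
      int x = X(i, j);
      bool o = x != NA_INTEGER;
      if (!o) has_missing = true; else ++M;
      Xc[(size_t)j * N + i] = o ? x : 0;
      Xr[(size_t)i * J + j] = o ? x : 0;
      obs_c[(size_t)j * N + i] = o;
      obs_r[(size_t)i * J + j] = o;
    }
  std::vector<double> llc((size_t)N * J, 0.0), llr((size_t)N * J, 0.0);
  for (int j = 0; j < J; ++j)
    for (int i = 0; i < N; ++i)
      if (obs_c[(size_t)j * N + i]) {
        double v = cell_ll(Xc[(size_t)j * N + i], theta[i], family, beta[j],
                           l1[j], l2[j], alpha[j], cpar[j], dpar[j]);
        llc[(size_t)j * N + i] = v;
        llr[(size_t)i * J + j] = v;
      }

  Adapt a_th(N, 1.0), a_be(J, 0.5), a_l1(J, 0.5), a_l2(J, 0.5),
        a_al(J, 0.3), a_c(J, 0.1), a_d(J, 0.1), a_s(2, 0.4),
        a_shift(1, 0.05);

  // storage --------------------------------------------------------------
  NumericMatrix out_theta(S, N), out_beta(S, J);
  NumericMatrix out_l1(sample_lambda ? S : 0, sample_lambda ? J : 0);
  NumericMatrix out_l2(sample_lambda ? S : 0, sample_lambda ? J : 0);
  NumericMatrix out_abc(family == 3 ? S : 0, family == 3 ? 3 * J : 0);
  NumericVector out_sb(sample_sb ? S : 0), out_sl(sample_lambda ? S : 0);
  NumericVector out_lltot(S);
  NumericMatrix out_pw(store_loglik ? S : 0, store_loglik ? M : 0);

  std::vector<double> buf(std::max(N, J));
  int batch = 0;

  // column update helper: propose new item-level value, scan column j ----
  // (lambda proposals restrict to one sign of eta, handled by `side`:
  //  0 = all cells, 1 = eta > 0 only, 2 = eta <= 0 only)
  // `side` restricts a lambda proposal to the cells it touches
  // (1 = eta > 0 only, 2 = eta <= 0 only, 0 = all); commit re-derives the
  // same mask, so beta/theta must not change between delta and commit.
  auto cell_active = [&](int j, int i, int side) -> bool {
    if (has_missing && !obs_c[(size_t)j * N + i]) return false;
    if (side) {
      double eta = theta[i] - beta[j];
      if (side == 1) return eta > 0.0;
      return eta <= 0.0;
    }
    return true;
  };
  auto col_delta = [&](int j, int side, double bj, double l1j, double l2j,
                       double aj, double cj, double dj) -> double {
    double d = 0.0;
    const double *ll = &llc[(size_t)j * N];
    const int *x = &Xc[(size_t)j * N];
    for (int i = 0; i < N; ++i) {
      if (!cell_active(j, i, side)) continue;
      buf[i] = cell_ll(x[i], theta[i], family, bj, l1j, l2j, aj, cj, dj);
      d += buf[i] - ll[i];
    }
    return d;
  };
  auto col_commit = [&](int j, int side) {
    double *ll = &llc[(size_t)j * N];
    for (int i = 0; i < N; ++i)
      if (cell_active(j, i, side)) { ll[i] = buf[i]; llr[(size_t)i * J + j] = buf[i]; }
  };

  for (int it = 0; it < n_iter; ++it) {
    // --- theta_i | rest : prior N(0,1) ---------------------------------
    for (int i = 0; i < N; ++i) {
      double prop = theta[i] + a_th.step[i] * norm_rand();
      double d = -0.5 * (prop * prop - theta[i] * theta[i]);
      const double *ll = &llr[(size_t)i * J];
      const int *x = &Xr[(size_t)i * J];
      const char *o = &obs_r[(size_t)i * J];
      for (int j = 0; j < J; ++j) {
        if (has_missing && !o[j]) continue;
        buf[j] = cell_ll(x[j], prop, family, beta[j], l1[j], l2[j],
                         alpha[j], cpar[j], dpar[j]);
        d += buf[j] - ll[j];
      }
      a_th.tries[i]++;
      if (std::log(unif_rand()) < d) {
        theta[i] = prop; a_th.acc[i]++;
        double *llw = &llr[(size_t)i * J];
        for (int j = 0; j < J; ++j)
          if (!has_missing || o[j]) { llw[j] = buf[j]; llc[(size_t)j * N + i] = buf[j]; }
      }
    }

    // --- item parameters: several sweeps per iteration ------------------
    // Item blocks cost one column scan each (cheap next to the ability
    // sweep) and beta/lambda are the slowest-mixing directions, so they
    // are refreshed item_sweeps times per iteration.
    for (int sweep = 0; sweep < item_sweeps; ++sweep) {
    // --- beta_j | rest : prior N(0, sb^2) -------------------------------
    for (int j = 0; j < J; ++j) {
      double prop = beta[j] + a_be.step[j] * norm_rand();
      double d = -0.5 * (prop * prop - beta[j] * beta[j]) / (sb * sb)
               + col_delta(j, 0, prop, l1[j], l2[j], alpha[j], cpar[j], dpar[j]);
      a_be.tries[j]++;
      if (std::log(unif_rand()) < d) { a_be.acc[j]++; col_commit(j, 0); beta[j] = prop; }
    }

    // --- lambda_{1j}, lambda_{2j} on u = log(1 + lambda) ----------------
    // Truncated-normal prior N(0, sl^2) I(-1, inf); the truncation
    // normalizer does not involve lambda and cancels here.  Jacobian of
    // lambda = exp(u) - 1 contributes +u.
    if (family == 0 && sample_lambda) {
      for (int j = 0; j < J; ++j) {
        double u = std::log1p(l1[j]);
        double up = u + a_l1.step[j] * norm_rand();
        double lp = std::expm1(up);
        double d = -0.5 * (lp * lp - l1[j] * l1[j]) / (sl * sl) + (up - u)
                 + col_delta(j, 1, beta[j], lp, l2[j], 1, 0, 1);
        a_l1.tries[j]++;
        if (std::log(unif_rand()) < d) { a_l1.acc[j]++; col_commit(j, 1); l1[j] = lp; }

        u = std::log1p(l2[j]);
        up = u + a_l2.step[j] * norm_rand();
        lp = std::expm1(up);
        d = -0.5 * (lp * lp - l2[j] * l2[j]) / (sl * sl) + (up - u)
          + col_delta(j, 2, beta[j], l1[j], lp, 1, 0, 1);
        a_l2.tries[j]++;
        if (std::log(unif_rand()) < d) { a_l2.acc[j]++; col_commit(j, 2); l2[j] = lp; }
      }
    }

    // --- 3PL/4PL item parameters ---------------------------------------
    if (family == 3) {
      for (int j = 0; j < J; ++j) {
        // log alpha ~ N(0,1); sample on the log scale directly
        double w = std::log(alpha[j]);
        double wp = w + a_al.step[j] * norm_rand();
        double d = -0.5 * (wp * wp - w * w)
                 + col_delta(j, 0, beta[j], 0, 0, std::exp(wp), cpar[j], dpar[j]);
        a_al.tries[j]++;
        if (std::log(unif_rand()) < d) { alpha[j] = std::exp(wp); a_al.acc[j]++; col_commit(j, 0); }

        // c ~ U(0, 0.5): flat prior, proposals outside the support reject
        double cp = cpar[j] + a_c.step[j] * norm_rand();
        a_c.tries[j]++;
        if (cp > 0.0 && cp < 0.5) {
          d = col_delta(j, 0, beta[j], 0, 0, alpha[j], cp, dpar[j]);
          if (std::log(unif_rand()) < d) { cpar[j] = cp; a_c.acc[j]++; col_commit(j, 0); }
        }

        // d ~ U(0.5, 1) (4PL only)
        if (sample_d) {
          double dp = dpar[j] + a_d.step[j] * norm_rand();
          a_d.tries[j]++;
          if (dp > 0.5 && dp < 1.0) {
            d = col_delta(j, 0, beta[j], 0, 0, alpha[j], cpar[j], dp);
            if (std::log(unif_rand()) < d) { dpar[j] = dp; a_d.acc[j]++; col_commit(j, 0); }
          }
        }
      }
    }

    } // end item sweeps

    // --- joint translation move ----------------------------------------
    // Only theta - beta enters the likelihood in every family, so the
    // common location of (theta, beta) is identified by the priors alone
    // and mixes slowly under scalar updates.  Shifting both blocks by the
    // same delta leaves the likelihood (and the caches) exactly invariant
    // and is accepted on the prior ratio only.
    {
      double delta = a_shift.step[0] * norm_rand();
      double d = 0.0;
      for (int i = 0; i < N; ++i)
        d += -0.5 * ((theta[i] + delta) * (theta[i] + delta)
                     - theta[i] * theta[i]);
      for (int j = 0; j < J; ++j)
        d += -0.5 * ((beta[j] + delta) * (beta[j] + delta)
                     - beta[j] * beta[j]) / (sb * sb);
      a_shift.tries[0]++;
      if (std::log(unif_rand()) < d) {
        a_shift.acc[0]++;
        for (int i = 0; i < N; ++i) theta[i] += delta;
        for (int j = 0; j < J; ++j) beta[j] += delta;
      }
    }

    // --- sigma_beta : half-Cauchy(0, 5), random walk on log sigma -------
    if (sample_sb) {
      double v = std::log(sb), vp = v + a_s.step[0] * norm_rand();
      double sbp = std::exp(vp);
      double d = (vp - v);  // Jacobian
      d += -std::log1p((sbp / 5.0) * (sbp / 5.0)) + std::log1p((sb / 5.0) * (sb / 5.0));
      for (int j = 0; j < J; ++j)
        d += (-std::log(sbp) - 0.5 * beta[j] * beta[j] / (sbp * sbp))
           - (-std::log(sb) - 0.5 * beta[j] * beta[j] / (sb * sb));
      a_s.tries[0]++;
      if (std::log(unif_rand()) < d) { sb = sbp; a_s.acc[0]++; }
    }

    // --- sigma_lambda : truncation normalizer depends on sigma ----------
    if (family == 0 && sample_lambda) {
      double v = std::log(sl), vp = v + a_s.step[1] * norm_rand();
      double slp = std::exp(vp);
      double d = (vp - v);
      d += -std::log1p((slp / 5.0) * (slp / 5.0)) + std::log1p((sl / 5.0) * (sl / 5.0));
      // log P(lambda > -1) = log(1 - Phi(-1/sigma)), upper-tail log form
      double lz_new = R::pnorm(-1.0 / slp, 0.0, 1.0, 0, 1);
      double lz_old = R::pnorm(-1.0 / sl, 0.0, 1.0, 0, 1);
      for (int j = 0; j < J; ++j) {
        d += (-std::log(slp) - 0.5 * l1[j] * l1[j] / (slp * slp) - lz_new)
           - (-std::log(sl) - 0.5 * l1[j] * l1[j] / (sl * sl) - lz_old);
        d += (-std::log(slp) - 0.5 * l2[j] * l2[j] / (slp * slp) - lz_new)
           - (-std::log(sl) - 0.5 * l2[j] * l2[j] / (sl * sl) - lz_old);
      }
      a_s.tries[1]++;
      if (std::log(unif_rand()) < d) { sl = slp; a_s.acc[1]++; }
    }

    // --- adaptation (burn-in only) --------------------------------------
    if (it < n_burnin && (it + 1) % 50 == 0) {
      ++batch;
      a_th.update(batch); a_be.update(batch); a_l1.update(batch);
      a_l2.update(batch); a_al.update(batch); a_c.update(batch);
      a_d.update(batch); a_s.update(batch); a_shift.update(batch);
    }

    // --- record ----------------------------------------------------------
    if (it >= n_burnin) {
      int s = it - n_burnin;
      for (int i = 0; i < N; ++i) out_theta(s, i) = theta[i];
      for (int j = 0; j < J; ++j) out_beta(s, j) = beta[j];
      if (sample_lambda)
        for (int j = 0; j < J; ++j) { out_l1(s, j) = l1[j]; out_l2(s, j) = l2[j]; }
      if (family == 3)
        for (int j = 0; j < J; ++j) {
          out_abc(s, j) = alpha[j];
          out_abc(s, J + j) = cpar[j];
          out_abc(s, 2 * J + j) = dpar[j];
        }
      if (sample_sb) out_sb[s] = sb;
      if (sample_lambda) out_sl[s] = sl;
      double tot = 0.0;
      int m = 0;
      for (int j = 0; j < J; ++j) {
        const double *ll = &llc[(size_t)j * N];
        const char *o = &obs_c[(size_t)j * N];
        for (int i = 0; i < N; ++i)
          if (o[i]) {
            tot += ll[i];
            if (store_loglik) out_pw(s, m) = ll[i];
            ++m;
          }
      }
      out_lltot[s] = tot;
    }

    if ((it + 1) % 500 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["theta"] = out_theta, _["beta"] = out_beta,
    _["lambda1"] = out_l1, _["lambda2"] = out_l2,
    _["abc"] = out_abc,
    _["sigma_beta"] = out_sb, _["sigma_lambda"] = out_sl,
    _["loglik_total"] = out_lltot,
    _["pointwise"] = out_pw,
    _["n_obs"] = M);
}

// Vectorized Stukel transform, shared with the R-level link functions.
// [[Rcpp::export(name = ".h_glogit_vec")]]
NumericVector h_glogit_vec(NumericVector eta, double l1, double l2) {
  int n = eta.size();
  NumericVector out(n);
  for (int k = 0; k < n; ++k) out[k] = h_glogit(eta[k], l1, l2);
  return out;
}
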
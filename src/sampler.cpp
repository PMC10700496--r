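// Adaptive random-walk Metropolis-within-Gibbs samplers for the three
// Bayesian 2PL variants. Scalar proposal scales are tuned towards a 0.44
// acceptance rate during burn-in (Robbins-Monro) and frozen afterwards.
// All randomness comes from R's RNG, so chains are reproducible via
// set.seed() on the R side.

#include <Rcpp.h>
using namespace Rcpp;

static const int NA_CELL = NA_INTEGER;

// log(1 + exp(x)) without overflow
static inline double safe_log1pexp(double x) {
  return (x > 0.0) ? x + ::log1p(::exp(-x)) : ::log1p(::exp(x));
}

// Bernoulli log-likelihood of one cell; x = alpha * (theta - beta)
static inline double ll_cell(int y, double x) {
  double lse = safe_log1pexp(x);
  return (y == 1) ? x - lse : -lse;
}

// [[Rcpp::export(name = ".cpp_loglik_2pl")]]
double cpp_loglik_2pl(IntegerMatrix y, NumericVector alpha, NumericVector beta,
                      NumericVector theta) {
  int N = y.nrow(), I = y.ncol();
  double ll = 0.0;
  for (int i = 0; i < I; ++i) {
    double a = alpha[i], b = beta[i];
    for (int j = 0; j < N; ++j) {
      int yy = y(j, i);
      if (yy == NA_CELL) continue;
      ll += ll_cell(yy, a * (theta[j] - b));
    }
  }
  return ll;
}

static double person_ll(const IntegerMatrix &y, const std::vector<double> &alpha,
                        const std::vector<double> &beta, double th, int j) {
  int I = y.ncol();
  double ll = 0.0;
  for (int i = 0; i < I; ++i) {
    int yy = y(j, i);
    if (yy == NA_CELL) continue;
    ll += ll_cell(yy, alpha[i] * (th - beta[i]));
  }
  return ll;
}

static double item_ll(const IntegerMatrix &y, double a, double b,
                      const std::vector<double> &theta, int i) {
  int N = y.nrow();
  double ll = 0.0;
  for (int j = 0; j < N; ++j) {
    int yy = y(j, i);
    if (yy == NA_CELL) continue;
    ll += ll_cell(yy, a * (theta[j] - b));
  }
  return ll;
}

static double full_ll(const IntegerMatrix &y, const std::vector<double> &alpha,
                      const std::vector<double> &beta,
                      const std::vector<double> &theta) {
  int I = y.ncol();
  double ll = 0.0;
  for (int i = 0; i < I; ++i)
    ll += item_ll(y, alpha[i], beta[i], theta, i);
  return ll;
}

// Robbins-Monro step on a log proposal SD, clamped to a sane range
static inline void adapt(double &lsd, double acc_prob, double gamma) {
  lsd += gamma * (acc_prob - 0.44);
  if (lsd < -6.0) lsd = -6.0;
  if (lsd > 3.0) lsd = 3.0;
}

static inline double acc_prob_from(double logratio) {
  return (logratio >= 0.0) ? 1.0 : ::exp(logratio);
}

// families: 0 half-Cauchy, 1 Exponential, 2 inverse-Gamma on tau,
//           3 inverse-Gamma on tau^2
enum Family { HALF_CAUCHY = 0, EXPONENTIAL = 1, IG_TAU = 2, IG_TAU_SQ = 3 };

// log prior density of v = log(tau) under inverse-Gamma(a, b), incl. Jacobian
static inline double ig_logprior_v(double v, double a, double b, bool on_sq) {
  double tau = ::exp(v);
  if (on_sq) {
    double t2 = tau * tau;
    return -(a + 1.0) * ::log(t2) - b / t2 + ::log(2.0 * tau) + v;
  }
  return -(a + 1.0) * v - b / tau + v;
}

// ---------------------------------------------------------------------------
// Non-centered separation-strategy hierarchical 2PL
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_sample_hier2pl")]]
NumericMatrix sample_hier2pl(IntegerMatrix y, int family, double hp1, double hp2,
                             double eta, double mu_b_sd, int n_iter, int n_burn,
                             List init) {
  int N = y.nrow(), I = y.ncol();
  std::vector<double> theta = as<std::vector<double> >(init["theta"]);
  std::vector<double> xt1 = as<std::vector<double> >(init["xt1"]);
  std::vector<double> xt2 = as<std::vector<double> >(init["xt2"]);
  double mu_a = init["mu_a"], mu_b = init["mu_b"];
  double va = init["va"], vb = init["vb"];  // aux u, or log(tau) for IG
  double r = init["r"];
  bool on_sq = (family == IG_TAU_SQ);

  double v_hi = (family == HALF_CAUCHY) ? M_PI / 2.0
              : (family == EXPONENTIAL) ? 1.0 : R_PosInf;

  // derived quantities
  double tau_a, tau_b;
  std::vector<double> alpha(I), beta(I);
  double q = ::sqrt(1.0 - r * r);
  auto resolve_tau = [&](double v) -> double {
    switch (family) {
      case HALF_CAUCHY: return hp1 * ::tan(std::min(v, M_PI / 2.0 * (1 - 1e-12)));
      case EXPONENTIAL: return hp1 * (-::log(v));
      default: return ::exp(v);
    }
  };
  auto rebuild = [&]() {
    tau_a = resolve_tau(va);
    tau_b = resolve_tau(vb);
    q = ::sqrt(1.0 - r * r);
    for (int i = 0; i < I; ++i) {
      alpha[i] = ::exp(mu_a + tau_a * xt1[i]);
      beta[i] = mu_b + tau_b * (r * xt1[i] + q * xt2[i]);
    }
  };
  rebuild();
  double cur_ll = full_ll(y, alpha, beta, theta);

  // proposal log-SDs
  std::vector<double> ls_theta(N, ::log(0.8)), ls_x1(I, ::log(0.5)),
      ls_x2(I, ::log(0.5));
  double ls_mu_a = ::log(0.1), ls_mu_b = ::log(0.15), ls_va = ::log(0.2),
         ls_vb = ::log(0.2), ls_r = ::log(0.2);
  double ls_imu_a = ::log(0.3), ls_imu_b = ::log(0.3), ls_iva = ::log(0.3),
         ls_ivb = ::log(0.3), ls_ir = ::log(0.2);

  int n_keep = n_iter - n_burn;
  int P = 2 * I + N + 5;
  NumericMatrix out(n_keep, P);

  RNGScope scope;
  for (int it = 0; it < n_iter; ++it) {
    bool adapting = it < n_burn;
    double gamma = 2.0 / ::sqrt((double)(it + 1));

    // --- abilities
    for (int j = 0; j < N; ++j) {
      double prop = theta[j] + R::norm_rand() * ::exp(ls_theta[j]);
      double d = person_ll(y, alpha, beta, prop, j) -
                 person_ll(y, alpha, beta, theta[j], j) -
                 0.5 * (prop * prop - theta[j] * theta[j]);
      double ap = acc_prob_from(d);
      if (R::unif_rand() < ap) theta[j] = prop;
      if (adapting) adapt(ls_theta[j], ap, gamma);
    }
    cur_ll = full_ll(y, alpha, beta, theta);

    // --- item z-scores
    for (int i = 0; i < I; ++i) {
      // first component moves both alpha_i and beta_i
      double prop = xt1[i] + R::norm_rand() * ::exp(ls_x1[i]);
      double a_new = ::exp(mu_a + tau_a * prop);
      double b_new = mu_b + tau_b * (r * prop + q * xt2[i]);
      double d = item_ll(y, a_new, b_new, theta, i) -
                 item_ll(y, alpha[i], beta[i], theta, i) -
                 0.5 * (prop * prop - xt1[i] * xt1[i]);
      double ap = acc_prob_from(d);
      if (R::unif_rand() < ap) {
        xt1[i] = prop; alpha[i] = a_new; beta[i] = b_new;
      }
      if (adapting) adapt(ls_x1[i], ap, gamma);

      // second component moves beta_i only
      prop = xt2[i] + R::norm_rand() * ::exp(ls_x2[i]);
      b_new = mu_b + tau_b * (r * xt1[i] + q * prop);
      d = item_ll(y, alpha[i], b_new, theta, i) -
          item_ll(y, alpha[i], beta[i], theta, i) -
          0.5 * (prop * prop - xt2[i] * xt2[i]);
      ap = acc_prob_from(d);
      if (R::unif_rand() < ap) { xt2[i] = prop; beta[i] = b_new; }
      if (adapting) adapt(ls_x2[i], ap, gamma);
    }
    cur_ll = full_ll(y, alpha, beta, theta);

    // --- hyperparameters (each changes every item, so full re-evaluation)
    std::vector<double> a_new(I), b_new(I);

    { // mu_alpha, prior N(0, 1)
      double prop = mu_a + R::norm_rand() * ::exp(ls_mu_a);
      double f = ::exp(prop - mu_a);
      for (int i = 0; i < I; ++i) a_new[i] = alpha[i] * f;
      double ll_new = full_ll(y, a_new, beta, theta);
      double d = ll_new - cur_ll - 0.5 * (prop * prop - mu_a * mu_a);
      double ap = acc_prob_from(d);
      if (R::unif_rand() < ap) { mu_a = prop; alpha = a_new; cur_ll = ll_new; }
      if (adapting) adapt(ls_mu_a, ap, gamma);
    }
    { // mu_beta, prior N(0, mu_b_sd)
      double prop = mu_b + R::norm_rand() * ::exp(ls_mu_b);
      double sh = prop - mu_b;
      for (int i = 0; i < I; ++i) b_new[i] = beta[i] + sh;
      double ll_new = full_ll(y, alpha, b_new, theta);
      double v2 = mu_b_sd * mu_b_sd;
      double d = ll_new - cur_ll - 0.5 * (prop * prop - mu_b * mu_b) / v2;
      double ap = acc_prob_from(d);
      if (R::unif_rand() < ap) { mu_b = prop; beta = b_new; cur_ll = ll_new; }
      if (adapting) adapt(ls_mu_b, ap, gamma);
    }
    { // variance-component auxiliary for the discriminations
      double prop = va + R::norm_rand() * ::exp(ls_va);
      double ap = 0.0;
      bool inside = (family == IG_TAU || family == IG_TAU_SQ)
                      ? std::isfinite(prop)
                      : (prop > 0.0 && prop < v_hi);
      if (inside) {
        double tau_new = resolve_tau(prop);
        for (int i = 0; i < I; ++i) a_new[i] = ::exp(mu_a + tau_new * xt1[i]);
        double ll_new = full_ll(y, a_new, beta, theta);
        double dprior = 0.0;
        if (family == IG_TAU || family == IG_TAU_SQ)
          dprior = ig_logprior_v(prop, hp1, hp2, on_sq) -
                   ig_logprior_v(va, hp1, hp2, on_sq);
        double d = ll_new - cur_ll + dprior;
        ap = acc_prob_from(d);
        if (R::unif_rand() < ap) {
          va = prop; tau_a = tau_new; alpha = a_new; cur_ll = ll_new;
        }
      }
      if (adapting) adapt(ls_va, ap, gamma);
    }
    { // variance-component auxiliary for the difficulties
      double prop = vb + R::norm_rand() * ::exp(ls_vb);
      double ap = 0.0;
      bool inside = (family == IG_TAU || family == IG_TAU_SQ)
                      ? std::isfinite(prop)
                      : (prop > 0.0 && prop < v_hi);
      if (inside) {
        double tau_new = resolve_tau(prop);
        for (int i = 0; i < I; ++i)
          b_new[i] = mu_b + tau_new * (r * xt1[i] + q * xt2[i]);
        double ll_new = full_ll(y, alpha, b_new, theta);
        double dprior = 0.0;
        if (family == IG_TAU || family == IG_TAU_SQ)
          dprior = ig_logprior_v(prop, hp1, hp2, on_sq) -
                   ig_logprior_v(vb, hp1, hp2, on_sq);
        double d = ll_new - cur_ll + dprior;
        ap = acc_prob_from(d);
        if (R::unif_rand() < ap) {
          vb = prop; tau_b = tau_new; beta = b_new; cur_ll = ll_new;
        }
      }
      if (adapting) adapt(ls_vb, ap, gamma);
    }
    // --- interweaving (ancillarity-sufficiency) moves: move a hyperparameter
    // and compensate the z-scores so alpha and beta are unchanged; the
    // likelihood cancels and only prior terms enter the acceptance ratio.
    // These break the strong grand-mean / z-score coupling that slows the
    // plain non-centered updates as the data grow.
    { // shift mu_beta, translate the second z-score component
      double dshift = R::norm_rand() * ::exp(ls_imu_b);
      double prop = mu_b + dshift;
      double comp = dshift / (tau_b * q);
      double v2 = mu_b_sd * mu_b_sd;
      double dlp = -0.5 * (prop * prop - mu_b * mu_b) / v2;
      for (int i = 0; i < I; ++i) {
        double z_new = xt2[i] - comp;
        dlp -= 0.5 * (z_new * z_new - xt2[i] * xt2[i]);
      }
      double ap = acc_prob_from(dlp);
      if (R::unif_rand() < ap) {
        mu_b = prop;
        for (int i = 0; i < I; ++i) xt2[i] -= comp;
      }
      if (adapting) adapt(ls_imu_b, ap, gamma);
    }
    { // shift mu_alpha, translate xt1 and shear xt2 so beta stays fixed too
      double dshift = R::norm_rand() * ::exp(ls_imu_a);
      double prop = mu_a + dshift;
      double c1 = dshift / tau_a;
      double c2 = (r / q) * c1;
      double dlp = -0.5 * (prop * prop - mu_a * mu_a);
      for (int i = 0; i < I; ++i) {
        double z1 = xt1[i] - c1, z2 = xt2[i] + c2;
        dlp -= 0.5 * (z1 * z1 - xt1[i] * xt1[i] + z2 * z2 - xt2[i] * xt2[i]);
      }
      double ap = acc_prob_from(dlp);
      if (R::unif_rand() < ap) {
        mu_a = prop;
        for (int i = 0; i < I; ++i) { xt1[i] -= c1; xt2[i] += c2; }
      }
      if (adapting) adapt(ls_imu_a, ap, gamma);
    }
    { // rescale tau_alpha, rescaling xt1 (and shearing xt2) to fix alpha, beta
      double prop = va + R::norm_rand() * ::exp(ls_iva);
      double ap = 0.0;
      bool inside = (family == IG_TAU || family == IG_TAU_SQ)
                      ? std::isfinite(prop)
                      : (prop > 0.0 && prop < v_hi);
      if (inside) {
        double tau_new = resolve_tau(prop);
        double f = tau_a / tau_new;   // xt1' = f * xt1
        double dlp = I * ::log(f);    // log-Jacobian of the rescaling
        if (family == IG_TAU || family == IG_TAU_SQ)
          dlp += ig_logprior_v(prop, hp1, hp2, on_sq) -
                 ig_logprior_v(va, hp1, hp2, on_sq);
        for (int i = 0; i < I; ++i) {
          double z1 = f * xt1[i];
          double z2 = xt2[i] + (r / q) * (xt1[i] - z1);
          dlp -= 0.5 * (z1 * z1 - xt1[i] * xt1[i] + z2 * z2 - xt2[i] * xt2[i]);
        }
        ap = acc_prob_from(dlp);
        if (R::unif_rand() < ap) {
          for (int i = 0; i < I; ++i) {
            double z1 = f * xt1[i];
            xt2[i] += (r / q) * (xt1[i] - z1);
            xt1[i] = z1;
          }
          va = prop; tau_a = tau_new;
        }
      }
      if (adapting) adapt(ls_iva, ap, gamma);
    }
    { // rescale tau_beta, absorbing the change into xt2 so beta stays fixed
      double prop = vb + R::norm_rand() * ::exp(ls_ivb);
      double ap = 0.0;
      bool inside = (family == IG_TAU || family == IG_TAU_SQ)
                      ? std::isfinite(prop)
                      : (prop > 0.0 && prop < v_hi);
      if (inside) {
        double tau_new = resolve_tau(prop);
        double f = tau_b / tau_new;
        double dlp = I * ::log(f);    // per-coordinate scaling Jacobian
        if (family == IG_TAU || family == IG_TAU_SQ)
          dlp += ig_logprior_v(prop, hp1, hp2, on_sq) -
                 ig_logprior_v(vb, hp1, hp2, on_sq);
        for (int i = 0; i < I; ++i) {
          double z2 = (f * (r * xt1[i] + q * xt2[i]) - r * xt1[i]) / q;
          dlp -= 0.5 * (z2 * z2 - xt2[i] * xt2[i]);
        }
        ap = acc_prob_from(dlp);
        if (R::unif_rand() < ap) {
          for (int i = 0; i < I; ++i)
            xt2[i] = (f * (r * xt1[i] + q * xt2[i]) - r * xt1[i]) / q;
          vb = prop; tau_b = tau_new;
        }
      }
      if (adapting) adapt(ls_ivb, ap, gamma);
    }
    { // move the correlation, compensating xt2 so beta stays fixed
      double prop = r + R::norm_rand() * ::exp(ls_ir);
      double ap = 0.0;
      if (prop > -1.0 && prop < 1.0) {
        double q_new = ::sqrt(1.0 - prop * prop);
        double dlp = I * ::log(q / q_new) +
                     (eta - 1.0) * (::log(1.0 - prop * prop) - ::log(1.0 - r * r));
        for (int i = 0; i < I; ++i) {
          double z2 = (r * xt1[i] + q * xt2[i] - prop * xt1[i]) / q_new;
          dlp -= 0.5 * (z2 * z2 - xt2[i] * xt2[i]);
        }
        ap = acc_prob_from(dlp);
        if (R::unif_rand() < ap) {
          for (int i = 0; i < I; ++i)
            xt2[i] = (r * xt1[i] + q * xt2[i] - prop * xt1[i]) / q_new;
          r = prop; q = q_new;
        }
      }
      if (adapting) adapt(ls_ir, ap, gamma);
    }

    { // item-parameter correlation; LKJ(eta) implies p(r) propto (1-r^2)^(eta-1)
      double prop = r + R::norm_rand() * ::exp(ls_r);
      double ap = 0.0;
      if (prop > -1.0 && prop < 1.0) {
        double q_new = ::sqrt(1.0 - prop * prop);
        for (int i = 0; i < I; ++i)
          b_new[i] = mu_b + tau_b * (prop * xt1[i] + q_new * xt2[i]);
        double ll_new = full_ll(y, alpha, b_new, theta);
        double d = ll_new - cur_ll +
                   (eta - 1.0) * (::log(1.0 - prop * prop) - ::log(1.0 - r * r));
        ap = acc_prob_from(d);
        if (R::unif_rand() < ap) {
          r = prop; q = q_new; beta = b_new; cur_ll = ll_new;
        }
      }
      if (adapting) adapt(ls_r, ap, gamma);
    }

    if (it >= n_burn) {
      int row = it - n_burn;
      for (int i = 0; i < I; ++i) out(row, i) = alpha[i];
      for (int i = 0; i < I; ++i) out(row, I + i) = beta[i];
      for (int j = 0; j < N; ++j) out(row, 2 * I + j) = theta[j];
      out(row, 2 * I + N + 0) = mu_a;
      out(row, 2 * I + N + 1) = mu_b;
      out(row, 2 * I + N + 2) = tau_a;
      out(row, 2 * I + N + 3) = tau_b;
      out(row, 2 * I + N + 4) = r;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Centered hierarchical 2PL with inverse-Wishart covariance prior
// ---------------------------------------------------------------------------

// 2x2 symmetric inverse
static inline void inv2(double s11, double s12, double s22, double &p11,
                        double &p12, double &p22) {
  double det = s11 * s22 - s12 * s12;
  p11 = s22 / det; p12 = -s12 / det; p22 = s11 / det;
}

// draw Sigma ~ IW(nu, A) via the Bartlett decomposition of W ~ Wishart(nu, A^-1)
static void riw2(double nu, double a11, double a12, double a22, double &s11,
                 double &s12, double &s22) {
  double p11, p12, p22;
  inv2(a11, a12, a22, p11, p12, p22);          // A^-1
  double l11 = ::sqrt(p11), l21 = p12 / l11;   // lower Cholesky of A^-1
  double l22 = ::sqrt(p22 - l21 * l21);
  double t11 = ::sqrt(R::rchisq(nu));
  double t22 = ::sqrt(R::rchisq(nu - 1.0));
  double t21 = R::norm_rand();
  // L_W = L * T (lower); W = L_W L_W'
  double w11c = l11 * t11;
  double w21c = l21 * t11 + l22 * t21;
  double w22c = l22 * t22;
  double w11 = w11c * w11c;
  double w12 = w11c * w21c;
  double w22 = w21c * w21c + w22c * w22c;
  inv2(w11, w12, w22, s11, s12, s22);          // Sigma = W^-1
}

// [[Rcpp::export(name = ".cpp_sample_iw2pl")]]
NumericMatrix sample_iw2pl(IntegerMatrix y, double iw_df, NumericMatrix iw_scale,
                           double mu_b_sd, int n_iter, int n_burn, List init) {
  int N = y.nrow(), I = y.ncol();
  std::vector<double> theta = as<std::vector<double> >(init["theta"]);
  std::vector<double> la = as<std::vector<double> >(init["log_alpha"]);
  std::vector<double> bb = as<std::vector<double> >(init["beta"]);
  double mu1 = init["mu_a"], mu2 = init["mu_b"];
  double s11 = init["s11"], s12 = init["s12"], s22 = init["s22"];

  std::vector<double> alpha(I);
  for (int i = 0; i < I; ++i) alpha[i] = ::exp(la[i]);
  double p11, p12, p22;
  inv2(s11, s12, s22, p11, p12, p22);

  std::vector<double> ls_theta(N, ::log(0.8)), ls_la(I, ::log(0.3)),
      ls_bb(I, ::log(0.3));

  int n_keep = n_iter - n_burn;
  NumericMatrix out(n_keep, 2 * I + N + 5);

  RNGScope scope;
  for (int it = 0; it < n_iter; ++it) {
    bool adapting = it < n_burn;
    double gamma = 2.0 / ::sqrt((double)(it + 1));

    for (int j = 0; j < N; ++j) {
      double prop = theta[j] + R::norm_rand() * ::exp(ls_theta[j]);
      double d = person_ll(y, alpha, bb, prop, j) -
                 person_ll(y, alpha, bb, theta[j], j) -
                 0.5 * (prop * prop - theta[j] * theta[j]);
      double ap = acc_prob_from(d);
      if (R::unif_rand() < ap) theta[j] = prop;
      if (adapting) adapt(ls_theta[j], ap, gamma);
    }

    auto prior_q = [&](double x1, double x2) {
      double d1 = x1 - mu1, d2 = x2 - mu2;
      return 0.5 * (p11 * d1 * d1 + 2.0 * p12 * d1 * d2 + p22 * d2 * d2);
    };

    for (int i = 0; i < I; ++i) {
      double prop = la[i] + R::norm_rand() * ::exp(ls_la[i]);
      double a_new = ::exp(prop);
      double d = item_ll(y, a_new, bb[i], theta, i) -
                 item_ll(y, alpha[i], bb[i], theta, i) +
                 prior_q(la[i], bb[i]) - prior_q(prop, bb[i]);
      double ap = acc_prob_from(d);
      if (R::unif_rand() < ap) { la[i] = prop; alpha[i] = a_new; }
      if (adapting) adapt(ls_la[i], ap, gamma);

      prop = bb[i] + R::norm_rand() * ::exp(ls_bb[i]);
      d = item_ll(y, alpha[i], prop, theta, i) -
          item_ll(y, alpha[i], bb[i], theta, i) +
          prior_q(la[i], bb[i]) - prior_q(la[i], prop);
      ap = acc_prob_from(d);
      if (R::unif_rand() < ap) bb[i] = prop;
      if (adapting) adapt(ls_bb[i], ap, gamma);
    }

    { // Gibbs draw of the grand means; priors N(0,1) and N(0, mu_b_sd)
      double sum1 = 0.0, sum2 = 0.0;
      for (int i = 0; i < I; ++i) { sum1 += la[i]; sum2 += bb[i]; }
      double q11 = 1.0 + I * p11, q12 = I * p12,
             q22 = 1.0 / (mu_b_sd * mu_b_sd) + I * p22;
      double r1 = p11 * sum1 + p12 * sum2, r2 = p12 * sum1 + p22 * sum2;
      double v11, v12, v22;
      inv2(q11, q12, q22, v11, v12, v22);      // posterior covariance
      double m1 = v11 * r1 + v12 * r2, m2 = v12 * r1 + v22 * r2;
      double c11 = ::sqrt(v11), c21 = v12 / c11,
             c22 = ::sqrt(v22 - c21 * c21);
      double z1 = R::norm_rand(), z2 = R::norm_rand();
      mu1 = m1 + c11 * z1;
      mu2 = m2 + c21 * z1 + c22 * z2;
    }
    { // Gibbs draw of Sigma ~ IW(df + I, scale + scatter)
      double a11 = iw_scale(0, 0), a12 = iw_scale(0, 1), a22 = iw_scale(1, 1);
      for (int i = 0; i < I; ++i) {
        double d1 = la[i] - mu1, d2 = bb[i] - mu2;
        a11 += d1 * d1; a12 += d1 * d2; a22 += d2 * d2;
      }
      riw2(iw_df + I, a11, a12, a22, s11, s12, s22);
      inv2(s11, s12, s22, p11, p12, p22);
    }

    if (it >= n_burn) {
      int row = it - n_burn;
      for (int i = 0; i < I; ++i) out(row, i) = alpha[i];
      for (int i = 0; i < I; ++i) out(row, I + i) = bb[i];
      for (int j = 0; j < N; ++j) out(row, 2 * I + j) = theta[j];
      out(row, 2 * I + N + 0) = mu1;
      out(row, 2 * I + N + 1) = mu2;
      out(row, 2 * I + N + 2) = ::sqrt(s11);
      out(row, 2 * I + N + 3) = ::sqrt(s22);
      out(row, 2 * I + N + 4) = s12 / ::sqrt(s11 * s22);
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Nonhierarchical 2PL (independent priors), optionally with fixed items
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_sample_simple2pl")]]
NumericMatrix sample_simple2pl(IntegerMatrix y, double mu_b_sd, bool fix_items,
                               int n_iter, int n_burn, List init) {
  int N = y.nrow(), I = y.ncol();
  std::vector<double> theta = as<std::vector<double> >(init["theta"]);
  std::vector<double> la = as<std::vector<double> >(init["log_alpha"]);
  std::vector<double> bb = as<std::vector<double> >(init["beta"]);
  std::vector<double> alpha(I);
  for (int i = 0; i < I; ++i) alpha[i] = ::exp(la[i]);

  std::vector<double> ls_theta(N, ::log(0.8)), ls_la(I, ::log(0.3)),
      ls_bb(I, ::log(0.3));
  double v2 = mu_b_sd * mu_b_sd;

  int n_keep = n_iter - n_burn;
  NumericMatrix out(n_keep, 2 * I + N + 5);

  RNGScope scope;
  for (int it = 0; it < n_iter; ++it) {
    bool adapting = it < n_burn;
    double gamma = 2.0 / ::sqrt((double)(it + 1));

    for (int j = 0; j < N; ++j) {
      double prop = theta[j] + R::norm_rand() * ::exp(ls_theta[j]);
      double d = person_ll(y, alpha, bb, prop, j) -
                 person_ll(y, alpha, bb, theta[j], j) -
                 0.5 * (prop * prop - theta[j] * theta[j]);
      double ap = acc_prob_from(d);
      if (R::unif_rand() < ap) theta[j] = prop;
      if (adapting) adapt(ls_theta[j], ap, gamma);
    }

    if (!fix_items) {
      for (int i = 0; i < I; ++i) {
        // lognormal(0,1) on alpha = N(0,1) on log alpha
        double prop = la[i] + R::norm_rand() * ::exp(ls_la[i]);
        double a_new = ::exp(prop);
        double d = item_ll(y, a_new, bb[i], theta, i) -
                   item_ll(y, alpha[i], bb[i], theta, i) -
                   0.5 * (prop * prop - la[i] * la[i]);
        double ap = acc_prob_from(d);
        if (R::unif_rand() < ap) { la[i] = prop; alpha[i] = a_new; }
        if (adapting) adapt(ls_la[i], ap, gamma);

        prop = bb[i] + R::norm_rand() * ::exp(ls_bb[i]);
        d = item_ll(y, alpha[i], prop, theta, i) -
            item_ll(y, alpha[i], bb[i], theta, i) -
            0.5 * (prop * prop - bb[i] * bb[i]) / v2;
        ap = acc_prob_from(d);
        if (R::unif_rand() < ap) bb[i] = prop;
        if (adapting) adapt(ls_bb[i], ap, gamma);
      }
    }

    if (it >= n_burn) {
      int row = it - n_burn;
      for (int i = 0; i < I; ++i) out(row, i) = alpha[i];
      for (int i = 0; i < I; ++i) out(row, I + i) = bb[i];
      for (int j = 0; j < N; ++j) out(row, 2 * I + j) = theta[j];
      out(row, 2 * I + N + 0) = NA_REAL;
      out(row, 2 * I + N + 1) = NA_REAL;
      out(row, 2 * I + N + 2) = NA_REAL;
      out(row, 2 * I + N + 3) = NA_REAL;
      out(row, 2 * I + N + 4) = NA_REAL;
    }
  }
  return out;
}
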
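// Compiled evaluation of per-model log posteriors (unconstrained scale) and
// the adaptive random-walk Metropolis sampler.  The R-level quadrature
// oracle re-implements the same densities independently in R/quadrature.R;
// keep the two in sync when touching any formula here.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct ModelC {
  // effect_type: 0 point mass, 1 normal(mean, sd) on the analysis scale,
  //              2 normal(0, sd) declared on Cohen's d, pushed through
  //                d = 2*sinh(z) onto the Fisher z analysis scale
  int effect_type;
  double effect_value, effect_mean, effect_sd;
  int tau_type;              // 0 point mass at 0, 1 inverse-gamma(shape, scale)
  double tau_shape, tau_scale;
  int bias_type;             // 0 none, 1 selection, 2 PET, 3 PEESE
  int sided;                 // 1 or 2 (selection only)
  int direction;             // +1 / -1 (one-sided selection only)
  std::vector<double> cutoffs;
  double b_scale;            // half-Cauchy scale for the PET/PEESE slope

  int J() const { return bias_type == 1 ? (int)cutoffs.size() + 1 : 0; }
  int n_free() const {
    int d = 0;
    if (effect_type > 0) d++;
    if (tau_type > 0) d++;
    if (bias_type == 1) d += J() - 1;
    else if (bias_type > 1) d++;
    return d;
  }
};

ModelC parse_model(const List& m) {
  ModelC mc;
  mc.effect_type = as<int>(m["effect_type"]);
  mc.effect_value = as<double>(m["effect_value"]);
  mc.effect_mean = as<double>(m["effect_mean"]);
  mc.effect_sd = as<double>(m["effect_sd"]);
  mc.tau_type = as<int>(m["tau_type"]);
  mc.tau_shape = as<double>(m["tau_shape"]);
  mc.tau_scale = as<double>(m["tau_scale"]);
  mc.bias_type = as<int>(m["bias_type"]);
  mc.sided = as<int>(m["sided"]);
  mc.direction = as<int>(m["direction"]);
  mc.cutoffs = as<std::vector<double> >(m["cutoffs"]);
  mc.b_scale = as<double>(m["b_scale"]);
  return mc;
}

struct Theta {
  double mu, tau, b, logjac;
  std::vector<double> omega;   // length J for selection models
  bool ok;
};

// unconstrained layout: [mu][log tau][stick-breaking logits (J-1)][log b]
Theta constrain(const ModelC& m, const double* u) {
  Theta th;
  th.logjac = 0.0;
  th.ok = true;
  int i = 0;
  th.mu = (m.effect_type > 0) ? u[i++] : m.effect_value;
  if (m.tau_type > 0) {
    th.tau = std::exp(u[i]);
    th.logjac += u[i];
    i++;
  } else th.tau = 0.0;
  th.b = 0.0;
  if (m.bias_type == 1) {
    int J = m.J();
    std::vector<double> eta(J);
    double rem = 1.0;
    for (int k = 0; k < J - 1; k++) {
      double v = 1.0 / (1.0 + std::exp(-u[i]));
      // Jacobian of (logit sticks) -> simplex
      th.logjac += std::log(rem) + std::log(v) + std::log1p(-v);
      eta[k] = v * rem;
      rem *= (1.0 - v);
      i++;
    }
    eta[J - 1] = rem;
    th.omega.resize(J);
    double acc = 0.0;
    for (int k = J - 1; k >= 0; k--) {  // omega_j = sum_{i >= j} eta_i
      acc += eta[k];
      th.omega[k] = acc;
    }
    th.omega[0] = 1.0;
  } else if (m.bias_type > 1) {
    th.b = std::exp(u[i]);
    th.logjac += u[i];
    i++;
  }
  if (!std::isfinite(th.mu) || !std::isfinite(th.tau)) th.ok = false;
  return th;
}

double log_prior_c(const ModelC& m, const Theta& th) {
  double lp = 0.0;
  if (m.effect_type == 1) {
    lp += R::dnorm(th.mu, m.effect_mean, m.effect_sd, 1);
  } else if (m.effect_type == 2) {
    // prior declared on Cohen's d, exact change of variables d = 2 sinh(z)
    lp += R::dnorm(2.0 * std::sinh(th.mu), 0.0, m.effect_sd, 1) +
      std::log(2.0 * std::cosh(th.mu));
  }
  if (m.tau_type == 1) {
    if (th.tau <= 0.0) return R_NegInf;
    lp += m.tau_shape * std::log(m.tau_scale) - R::lgammafn(m.tau_shape) -
      (m.tau_shape + 1.0) * std::log(th.tau) - m.tau_scale / th.tau;
  }
  if (m.bias_type == 1) {
    lp += R::lgammafn((double)m.J());       // Dirichlet(1, ..., 1)
  } else if (m.bias_type > 1) {
    if (th.b < 0.0) return R_NegInf;
    lp += M_LN2 + R::dcauchy(th.b, 0.0, m.b_scale, 1);  // half-Cauchy
  }
  return lp;
}

double log_lik_c(const ModelC& m, const Theta& th,
                 const std::vector<double>& y, const std::vector<double>& se,
                 const std::vector<int>& memb) {
  const int K = (int)y.size();
  double ll = 0.0;
  if (m.bias_type != 1) {
    for (int k = 0; k < K; k++) {
      double mean = th.mu;
      if (m.bias_type == 2) mean += th.b * se[k];
      else if (m.bias_type == 3) mean += th.b * se[k] * se[k];
      double sd = std::sqrt(se[k] * se[k] + th.tau * th.tau);
      ll += R::dnorm(y[k], mean, sd, 1);
    }
    return ll;
  }
  // selection model: weighted density, per-study renormalisation
  const int J = m.J();
  const int nc = J - 1;
  // one-sided with negative direction mirrors the whole problem
  const double sgn = (m.sided == 1 && m.direction < 0) ? -1.0 : 1.0;
  const double mu = sgn * th.mu;
  for (int k = 0; k < K; k++) {
    double w = th.omega[memb[k] - 1];
    if (w <= 0.0) return R_NegInf;
    double sd = std::sqrt(se[k] * se[k] + th.tau * th.tau);
    double denom = 0.0;
    if (m.sided == 1) {
      // interval j in 1..J: t_j <= y < t_{j-1} with t_j = se * qnorm(1 - c_j)
      // (descending in j, t_0 = +inf); survivor S(t) = 1 - Phi((t - mu)/sd)
      double surv_prev = 0.0;  // S(t_0)
      for (int j = 0; j < nc; j++) {
        double t = se[k] * R::qnorm(1.0 - m.cutoffs[j], 0.0, 1.0, 1, 0);
        double surv = 1.0 - R::pnorm((t - mu) / sd, 0.0, 1.0, 1, 0);
        denom += th.omega[j] * (surv - surv_prev);
        surv_prev = surv;
      }
      denom += th.omega[J - 1] * (1.0 - surv_prev);
    } else {
      // two-sided: G(q) = P(|y| >= q)
      double g_prev = 0.0;
      for (int j = 0; j < nc; j++) {
        double q = se[k] * R::qnorm(1.0 - m.cutoffs[j] / 2.0, 0.0, 1.0, 1, 0);
        double g = (1.0 - R::pnorm((q - mu) / sd, 0.0, 1.0, 1, 0)) +
          R::pnorm((-q - mu) / sd, 0.0, 1.0, 1, 0);
        denom += th.omega[j] * (g - g_prev);
        g_prev = g;
      }
      denom += th.omega[J - 1] * (1.0 - g_prev);
    }
    if (denom <= 0.0) return R_NegInf;
    double yk = sgn * y[k];
    ll += std::log(w) + R::dnorm(yk, mu, sd, 1) - std::log(denom);
  }
  return ll;
}

double logpost_one(const ModelC& m, const double* u,
                   const std::vector<double>& y, const std::vector<double>& se,
                   const std::vector<int>& memb) {
  Theta th = constrain(m, u);
  if (!th.ok) return R_NegInf;
  double lp = log_prior_c(m, th);
  if (!std::isfinite(lp)) return R_NegInf;
  double ll = log_lik_c(m, th, y, se, memb);
  if (!std::isfinite(ll)) return R_NegInf;
  return ll + lp + th.logjac;
}

// lower-triangular Cholesky for small dense matrices; returns false if not SPD
bool chol_small(std::vector<double>& A, int d) {
  for (int j = 0; j < d; j++) {
    double s = A[j * d + j];
    for (int k = 0; k < j; k++) s -= A[j * d + k] * A[j * d + k];
    if (s <= 0.0) return false;
    A[j * d + j] = std::sqrt(s);
    for (int i = j + 1; i < d; i++) {
      double t = A[i * d + j];
      for (int k = 0; k < j; k++) t -= A[i * d + k] * A[j * d + k];
      A[i * d + j] = t / A[j * d + j];
    }
    for (int k = j + 1; k < d; k++) A[j * d + k] = 0.0;
  }
  return true;
}

}  // namespace

// [[Rcpp::export(name = ".cpp_logpost")]]
NumericVector cpp_logpost(NumericMatrix U, List model,
                          NumericVector y, NumericVector se,
                          IntegerVector memb) {
  ModelC m = parse_model(model);
  std::vector<double> yv = as<std::vector<double> >(y);
  std::vector<double> sev = as<std::vector<double> >(se);
  std::vector<int> mb = as<std::vector<int> >(memb);
  const int n = U.nrow();
  const int d = m.n_free();
  if (U.ncol() != d) stop("parameter matrix has %d columns, model has %d free parameters",
                          U.ncol(), d);
  NumericVector out(n);
  std::vector<double> u(d > 0 ? d : 1);
  for (int i = 0; i < n; i++) {
    for (int j = 0; j < d; j++) u[j] = U(i, j);
    out[i] = logpost_one(m, u.data(), yv, sev, mb);
  }
  return out;
}

// Joint adaptive random-walk Metropolis on the unconstrained scale.
// Adaptation (Haario covariance estimate + Robbins-Monro global scale) runs
// for n_adapt iterations and is then frozen, so the kept draws come from a
// fixed, valid Metropolis kernel.  Uses R's RNG: seeding via set.seed().
// [[Rcpp::export(name = ".cpp_amh")]]
List cpp_amh(List model, NumericVector y, NumericVector se, IntegerVector memb,
             NumericVector init, NumericMatrix S0,
             int n_adapt, int n_keep, int thin, double target_acc) {
  ModelC m = parse_model(model);
  std::vector<double> yv = as<std::vector<double> >(y);
  std::vector<double> sev = as<std::vector<double> >(se);
  std::vector<int> mb = as<std::vector<int> >(memb);
  const int d = m.n_free();
  if (d == 0) stop("model has no free parameters; nothing to sample");
  if ((int)init.size() != d) stop("init length mismatch");

  std::vector<double> u(init.begin(), init.end());
  double lp = logpost_one(m, u.data(), yv, sev, mb);
  if (!std::isfinite(lp)) stop("initial value has zero posterior density");

  // proposal: u' = u + exp(ls) * L z,  L = chol(cov)
  std::vector<double> L(d * d, 0.0);
  {
    std::vector<double> A(d * d);
    for (int i = 0; i < d; i++)
      for (int j = 0; j < d; j++) A[i * d + j] = S0(i, j);
    for (int i = 0; i < d; i++) A[i * d + i] += 1e-10;
    if (!chol_small(A, d)) {
      std::fill(A.begin(), A.end(), 0.0);
      for (int i = 0; i < d; i++) A[i * d + i] = 0.1;
    }
    L = A;
  }
  double ls = std::log(2.38 / std::sqrt((double)d));

  // Welford accumulators for the empirical covariance
  std::vector<double> mean(u), C(d * d, 0.0);
  long nw = 1;

  NumericMatrix draws(n_keep, d);
  std::vector<double> prop(d), z(d);
  long n_acc = 0, n_tot = 0;
  const long total = (long)n_adapt + (long)n_keep * thin;
  RNGScope scope;

  for (long t = 1; t <= total; t++) {
    for (int j = 0; j < d; j++) z[j] = R::norm_rand();
    double s = std::exp(ls);
    for (int i = 0; i < d; i++) {
      double acc = 0.0;
      for (int j = 0; j <= i; j++) acc += L[i * d + j] * z[j];
      prop[i] = u[i] + s * acc;
    }
    double lpp = logpost_one(m, prop.data(), yv, sev, mb);
    bool accept = std::isfinite(lpp) &&
      (lpp - lp >= 0.0 || R::unif_rand() < std::exp(lpp - lp));
    if (accept) { u = prop; lp = lpp; n_acc++; }
    n_tot++;

    if (t <= n_adapt) {
      double gam = std::min(0.05, 2.0 / std::sqrt((double)t));
      ls += gam * ((accept ? 1.0 : 0.0) - target_acc);
      // covariance update
      nw++;
      std::vector<double> delta(d);
      for (int j = 0; j < d; j++) delta[j] = u[j] - mean[j];
      for (int j = 0; j < d; j++) mean[j] += delta[j] / nw;
      for (int i = 0; i < d; i++)
        for (int j = 0; j < d; j++)
          C[i * d + j] += delta[i] * (u[j] - mean[j]);
      if (t % 100 == 0 && t >= 200) {
        std::vector<double> A(d * d);
        for (int i = 0; i < d * d; i++) A[i] = C[i] / (nw - 1);
        for (int i = 0; i < d; i++) A[i * d + i] += 1e-10;
        if (chol_small(A, d)) L = A;
      }
    } else {
      long tk = t - n_adapt;
      if (tk % thin == 0) {
        int row = (int)(tk / thin) - 1;
        for (int j = 0; j < d; j++) draws(row, j) = u[j];
      }
    }
  }
  return List::create(_["draws"] = draws,
                      _["acc_rate"] = (double)n_acc / (double)n_tot,
                      _["log_scale"] = ls);
}
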
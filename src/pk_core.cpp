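// Closed-form two-compartment infusion kinetics and the per-subject
// machinery behind MAP (empirical Bayes) estimation and the Laplace /
// FOCE-I marginal objective.  Everything here operates on a pre-built
// "subject grid": a partition of the subject's record into intervals of
// constant infusion rate / occasion / covariate status, with observations
// falling on interval ends.
//
// Random-effect vector layout per subject: [eta_cl][eta_v1][kappa_1..m],
// where components whose prior SD is fixed at zero are simply absent.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// pars vector positions (kept in sync with R/estimation.R)
#define P_THETA_CL 0
#define P_THETA_V1 1
#define P_FACT     2
#define P_EXP_CL   3
#define P_EXP_V    4
#define P_REF_WT   5
#define P_SIGMA    6
#define P_OMEGA_CL 7
#define P_OMEGA_V1 8
#define P_PI_CL    9

static const double F_FLOOR = 1e-9;  // guards log(sigma^2 f^2) at f = 0

// advance the linear 2-cmt system (amounts a1, a2) by dt under constant
// zero-order input 'rate'; exact via eigendecomposition of the 2x2 system
static inline void step_2cmt(double &a1, double &a2,
                             double cl, double v1, double q, double v2,
                             double rate, double dt) {
  if (dt <= 0.0) return;
  const double k10 = cl / v1, k12 = q / v1, k21 = q / v2;
  const double tr = -(k10 + k12 + k21), det = k10 * k21;
  // disc^2 = (k10+k12-k21)^2 + 4 k12 k21 > 0 whenever q, v2 > 0
  const double disc = std::sqrt(tr * tr - 4.0 * det);
  const double l1 = 0.5 * (tr + disc), l2 = 0.5 * (tr - disc);
  const double a1s = rate / k10, a2s = a1s * k12 / k21;
  const double d1 = a1 - a1s, d2 = a2 - a2s;
  const double E1 = std::exp(l1 * dt), E2 = std::exp(l2 * dt);
  const double c1 = (E1 - E2) / disc, c2 = (l1 * E2 - l2 * E1) / disc;
  a1 = a1s + c1 * (-(k10 + k12) * d1 + k21 * d2) + c2 * d1;
  a2 = a2s + c1 * (k12 * d1 - k21 * d2) + c2 * d2;
  if (a1 < 0.0 && a1 > -1e-12) a1 = 0.0;
  if (a2 < 0.0 && a2 > -1e-12) a2 = 0.0;
}

// [[Rcpp::export]]
NumericVector cpp_propagate(double a1, double a2, double cl, double v1,
                            double q, double v2, double rate, double dt) {
  step_2cmt(a1, a2, cl, v1, q, v2, rate, dt);
  return NumericVector::create(a1, a2);
}

struct SubGrid {
  arma::vec dt, rate, dv;
  arma::mat z;            // n_int x n_cov covariate values (CL multipliers)
  arma::ivec kidx;        // per-interval kappa index in b (or -1)
  arma::ivec obs_int;     // sorted 0-based interval index; obs at its end
  double weight;
  int has_eta_cl, has_eta_v1, n_kappa;
  int nb() const { return has_eta_cl + has_eta_v1 + n_kappa; }
};

static SubGrid unpack(const List &sub) {
  SubGrid g;
  g.dt      = as<arma::vec>(sub["dt"]);
  g.rate    = as<arma::vec>(sub["rate"]);
  g.dv      = as<arma::vec>(sub["dv"]);
  g.z       = as<arma::mat>(sub["z"]);
  g.kidx    = as<arma::ivec>(sub["kidx"]);
  g.obs_int = as<arma::ivec>(sub["obs_int"]);
  g.weight  = as<double>(sub["weight"]);
  g.has_eta_cl = as<int>(sub["has_eta_cl"]);
  g.has_eta_v1 = as<int>(sub["has_eta_v1"]);
  g.n_kappa    = as<int>(sub["n_kappa"]);
  return g;
}

// prior SDs for the active effect vector
static arma::vec prior_sd(const SubGrid &g, const arma::vec &pars) {
  arma::vec sd(g.nb());
  int j = 0;
  if (g.has_eta_cl) sd(j++) = pars(P_OMEGA_CL);
  if (g.has_eta_v1) sd(j++) = pars(P_OMEGA_V1);
  for (int k = 0; k < g.n_kappa; ++k) sd(j++) = pars(P_PI_CL);
  return sd;
}

static arma::vec ipred_core(const SubGrid &g, const arma::vec &pars,
                            const arma::vec &beta, const arma::vec &b) {
  const double w = g.weight, ref = pars(P_REF_WT), fact = pars(P_FACT);
  const double wcl = pars(P_THETA_CL) * std::pow(w / ref, pars(P_EXP_CL));
  const double wv1 = pars(P_THETA_V1) * std::pow(w / ref, pars(P_EXP_V));
  int j = 0;
  const double eta_cl = g.has_eta_cl ? b(j++) : 0.0;
  const double eta_v1 = g.has_eta_v1 ? b(j++) : 0.0;
  const int koff = j;
  const double v1 = wv1 * std::exp(eta_v1), v2 = v1 * fact;
  double a1 = 0.0, a2 = 0.0;
  arma::vec f(g.obs_int.n_elem, arma::fill::zeros);
  arma::uword op = 0;
  while (op < g.obs_int.n_elem && g.obs_int(op) < 0) ++op;  // pre-dose: 0
  const bool have_cov = beta.n_elem > 0 && g.z.n_cols > 0;
  for (arma::uword k = 0; k < g.dt.n_elem; ++k) {
    double covm = have_cov ? arma::dot(g.z.row(k).t(), beta) : 0.0;
    double kap = (g.kidx(k) >= 0) ? b(koff + g.kidx(k)) : 0.0;
    double cl = wcl * std::exp(covm + eta_cl + kap);
    step_2cmt(a1, a2, cl, v1, cl * fact, v2, g.rate(k), g.dt(k));
    while (op < g.obs_int.n_elem && g.obs_int(op) == (int)k) {
      f(op) = a1 / v1;
      ++op;
    }
  }
  return f;
}

// -2 log L(y | b): proportional residual error, fully normalized
static double deviance_core(const arma::vec &dv, const arma::vec &f,
                            double sigma) {
  double dev = 0.0;
  const double s2 = sigma * sigma;
  for (arma::uword k = 0; k < dv.n_elem; ++k) {
    double fe = std::max(f(k), F_FLOOR);
    double v = s2 * fe * fe;
    double e = dv(k) - f(k);
    dev += e * e / v + std::log(2.0 * M_PI * v);
  }
  return dev;
}

// penalized deviance g(b) = -2 log L(y|b) - 2 log p(b)
static double pdev_core(const SubGrid &g, const arma::vec &pars,
                        const arma::vec &beta, const arma::vec &b) {
  arma::vec f = ipred_core(g, pars, beta, b);
  double out = deviance_core(g.dv, f, pars(P_SIGMA));
  arma::vec sd = prior_sd(g, pars);
  for (arma::uword j = 0; j < sd.n_elem; ++j)
    out += b(j) * b(j) / (sd(j) * sd(j)) + std::log(2.0 * M_PI * sd(j) * sd(j));
  return out;
}

static arma::mat jac_core(const SubGrid &g, const arma::vec &pars,
                          const arma::vec &beta, const arma::vec &b,
                          double h = 1e-5) {
  const int nb = b.n_elem, nobs = g.obs_int.n_elem;
  arma::mat J(nobs, nb);
  arma::vec bp = b, bm = b;
  for (int j = 0; j < nb; ++j) {
    bp(j) = b(j) + h; bm(j) = b(j) - h;
    J.col(j) = (ipred_core(g, pars, beta, bp) -
                ipred_core(g, pars, beta, bm)) / (2.0 * h);
    bp(j) = b(j); bm(j) = b(j);
  }
  return J;
}

// gradient of g(b) using exact residual derivatives through a fd Jacobian
static arma::vec pdev_grad(const SubGrid &g, const arma::vec &pars,
                           const arma::vec &beta, const arma::vec &b,
                           const arma::vec &f, const arma::mat &J) {
  const double s2 = pars(P_SIGMA) * pars(P_SIGMA);
  arma::vec grad(b.n_elem, arma::fill::zeros);
  for (arma::uword k = 0; k < g.dv.n_elem; ++k) {
    double fe = std::max(f(k), F_FLOOR);
    double v = s2 * fe * fe;
    double e = g.dv(k) - f(k);
    // d/df of e^2/v + log v with v = s2 f^2 (interaction term included)
    double dd = -2.0 * e / v - 2.0 * e * e / (v * fe) + 2.0 / fe;
    grad += dd * J.row(k).t();
  }
  arma::vec sd = prior_sd(g, pars);
  for (arma::uword j = 0; j < sd.n_elem; ++j)
    grad(j) += 2.0 * b(j) / (sd(j) * sd(j));
  return grad;
}

// joint posterior mode of the subject's random effects by damped
// Gauss-Newton (Levenberg-Marquardt) on the penalized deviance
static List map_core(const SubGrid &g, const arma::vec &pars,
                     const arma::vec &beta, const arma::vec &b0,
                     int maxit, double gtol) {
  const int nb = g.nb();
  if (nb == 0) {
    arma::vec f = ipred_core(g, pars, beta, arma::vec());
    return List::create(_["b"] = NumericVector(0),
                        _["g"] = deviance_core(g.dv, f, pars(P_SIGMA)),
                        _["grad_norm"] = 0.0, _["iter"] = 0,
                        _["converged"] = true);
  }
  arma::vec sd = prior_sd(g, pars);
  arma::vec b = arma::zeros(nb);
  double gcur = pdev_core(g, pars, beta, b);
  if (b0.n_elem == (arma::uword)nb) {
    double g0 = pdev_core(g, pars, beta, b0);
    if (g0 < gcur) { b = b0; gcur = g0; }
  }
  const double s2 = pars(P_SIGMA) * pars(P_SIGMA);
  double lam = 1e-3, gnorm = R_PosInf;
  int it = 0;
  bool conv = false;
  for (it = 0; it < maxit; ++it) {
    arma::vec f = ipred_core(g, pars, beta, b);
    arma::mat J = jac_core(g, pars, beta, b);
    arma::vec grad = pdev_grad(g, pars, beta, b, f, J);
    gnorm = arma::abs(grad).max();
    if (gnorm < gtol) { conv = true; break; }
    // curvature of the penalized deviance: exact second derivative in
    // f-space times the Gauss-Newton outer product (curvature of f in b
    // is dropped); LM damping absorbs any indefiniteness
    arma::mat H(nb, nb, arma::fill::zeros);
    for (arma::uword k = 0; k < g.dv.n_elem; ++k) {
      double fe = std::max(f(k), F_FLOOR);
      double v = s2 * fe * fe;
      double e = g.dv(k) - f(k);
      double d2 = 2.0 / v + 8.0 * e / (v * fe) + 6.0 * e * e / (v * fe * fe)
                  - 2.0 / (fe * fe);
      H += d2 * (J.row(k).t() * J.row(k));
    }
    for (int j = 0; j < nb; ++j) H(j, j) += 2.0 / (sd(j) * sd(j));
    bool accepted = false;
    for (int tries = 0; tries < 18; ++tries) {
      arma::mat Hd = H;
      for (int j = 0; j < nb; ++j)
        Hd(j, j) += lam * std::max(std::abs(H(j, j)), 1e-8);
      arma::vec step;
      bool ok = arma::solve(step, Hd, -grad, arma::solve_opts::likely_sympd +
                                             arma::solve_opts::no_approx);
      if (ok) {
        arma::vec bn = b + step;
        double gn = pdev_core(g, pars, beta, bn);
        if (std::isfinite(gn) && gn < gcur) {
          b = bn; gcur = gn;
          lam = std::max(lam / 3.0, 1e-10);
          accepted = true;
          break;
        }
      }
      lam *= 8.0;
    }
    if (!accepted) break;  // stuck: gradient may still be above tol
  }
  return List::create(_["b"] = wrap(b), _["g"] = gcur,
                      _["grad_norm"] = gnorm, _["iter"] = it,
                      _["converged"] = conv || gnorm < 1e-3);
}

// FOCE-I subject objective at the mode: linearize f around bhat, marginal
// covariance V = J Omega J' + diag(sigma^2 f^2), residual r = y - f + J bhat
static double ofv_foce(const SubGrid &g, const arma::vec &pars,
                       const arma::vec &beta, const arma::vec &bhat) {
  arma::vec f = ipred_core(g, pars, beta, bhat);
  const int n = f.n_elem;
  const double s2 = pars(P_SIGMA) * pars(P_SIGMA);
  arma::vec fe = arma::clamp(f, F_FLOOR, arma::datum::inf);
  arma::mat V = arma::diagmat(s2 * fe % fe);
  arma::vec r = g.dv - f;
  if (g.nb() > 0) {
    arma::mat J = jac_core(g, pars, beta, bhat);
    arma::vec sd = prior_sd(g, pars);
    V += J * arma::diagmat(sd % sd) * J.t();
    r += J * bhat;
  }
  arma::mat L;
  if (!arma::chol(L, V, "lower")) {
    V.diag() += 1e-8 * arma::mean(V.diag());
    if (!arma::chol(L, V, "lower")) return R_PosInf;
  }
  arma::vec u = arma::solve(arma::trimatl(L), r);
  double logdet = 2.0 * arma::accu(arma::log(L.diag()));
  return n * std::log(2.0 * M_PI) + logdet + arma::dot(u, u);
}

// full Laplace: g(bhat) - nb log(2 pi) + log det( Hess(g)/2 ).  The Hessian
// is obtained by central differences of the (exact-given-J) gradient, which
// is much smoother in the population parameters than double differencing
// of the objective — the outer optimizer relies on that smoothness.
static double ofv_laplace(const SubGrid &g, const arma::vec &pars,
                          const arma::vec &beta, const arma::vec &bhat) {
  const int nb = g.nb();
  double g0 = pdev_core(g, pars, beta, bhat);
  if (nb == 0) return g0;
  const double h = 1e-4;
  arma::mat H(nb, nb);
  arma::vec bp;
  for (int j = 0; j < nb; ++j) {
    bp = bhat; bp(j) += h;
    arma::vec fp = ipred_core(g, pars, beta, bp);
    arma::vec gp = pdev_grad(g, pars, beta, bp, fp,
                             jac_core(g, pars, beta, bp));
    bp = bhat; bp(j) -= h;
    arma::vec fm = ipred_core(g, pars, beta, bp);
    arma::vec gm = pdev_grad(g, pars, beta, bp, fm,
                             jac_core(g, pars, beta, bp));
    H.col(j) = (gp - gm) / (2.0 * h);
  }
  arma::mat G = 0.25 * (H + H.t());  // Hess(g)/2, symmetrized
  arma::mat L;
  if (!arma::chol(L, G, "lower")) {
    G.diag() += 1e-6 * std::max(1.0, arma::abs(G.diag()).max());
    if (!arma::chol(L, G, "lower")) return R_PosInf;
  }
  return g0 - nb * std::log(2.0 * M_PI) +
         2.0 * arma::accu(arma::log(L.diag()));
}

// terminal amounts (a1, a2) after traversing the whole grid
// [[Rcpp::export]]
NumericVector cpp_sub_state(List sub, NumericVector pars, NumericVector beta,
                            NumericVector b_) {
  SubGrid g = unpack(sub);
  arma::vec p = as<arma::vec>(pars), bt = as<arma::vec>(beta),
            b = as<arma::vec>(b_);
  const double w = g.weight, ref = p(P_REF_WT), fact = p(P_FACT);
  const double wcl = p(P_THETA_CL) * std::pow(w / ref, p(P_EXP_CL));
  const double wv1 = p(P_THETA_V1) * std::pow(w / ref, p(P_EXP_V));
  int j = 0;
  const double eta_cl = g.has_eta_cl ? b(j++) : 0.0;
  const double eta_v1 = g.has_eta_v1 ? b(j++) : 0.0;
  const int koff = j;
  const double v1 = wv1 * std::exp(eta_v1), v2 = v1 * fact;
  double a1 = 0.0, a2 = 0.0;
  const bool have_cov = bt.n_elem > 0 && g.z.n_cols > 0;
  for (arma::uword k = 0; k < g.dt.n_elem; ++k) {
    double covm = have_cov ? arma::dot(g.z.row(k).t(), bt) : 0.0;
    double kap = (g.kidx(k) >= 0) ? b(koff + g.kidx(k)) : 0.0;
    double cl = wcl * std::exp(covm + eta_cl + kap);
    step_2cmt(a1, a2, cl, v1, cl * fact, v2, g.rate(k), g.dt(k));
  }
  return NumericVector::create(a1, a2, v1);
}

// ---------------------------------------------------------------------
// Quadrature-filter marginal likelihood ("agq"): adaptive Gauss-Hermite
// over the subject-level effects; conditional on them, the occasion
// effects are integrated occasion-by-occasion with Gauss-Hermite nodes on
// kappa while the drug-amount state is carried as a Gaussian (the
// dynamics are linear given kappa; the node mixture is collapsed by
// moment matching at each occasion boundary).  With IOV off this is exact
// adaptive quadrature of a linear-Gaussian model.

// affine step: a(t+dt) = Phi a(t) + cvec
static inline void step_matrix(double cl, double v1, double q, double v2,
                               double rate, double dt,
                               arma::mat22 &Phi, arma::vec2 &cvec) {
  const double k10 = cl / v1, k12 = q / v1, k21 = q / v2;
  const double tr = -(k10 + k12 + k21), det = k10 * k21;
  const double disc = std::sqrt(tr * tr - 4.0 * det);
  const double l1 = 0.5 * (tr + disc), l2 = 0.5 * (tr - disc);
  const double E1 = std::exp(l1 * dt), E2 = std::exp(l2 * dt);
  const double c1 = (E1 - E2) / disc, c2 = (l1 * E2 - l2 * E1) / disc;
  Phi(0, 0) = c1 * (-(k10 + k12)) + c2;
  Phi(0, 1) = c1 * k21;
  Phi(1, 0) = c1 * k12;
  Phi(1, 1) = c1 * (-k21) + c2;
  arma::vec2 s;
  s(0) = rate / k10;
  s(1) = s(0) * k12 / k21;
  cvec = s - Phi * s;
}

// Gauss-Hermite rule for E[f(Z)], Z ~ N(0,1) (Golub-Welsch on the
// probabilists' recurrence), cached per size
static void gh_rule(int n, arma::vec &x, arma::vec &w) {
  arma::mat J(n, n, arma::fill::zeros);
  for (int i = 0; i + 1 < n; ++i)
    J(i, i + 1) = J(i + 1, i) = std::sqrt((double)(i + 1));
  arma::vec ev;
  arma::mat V;
  arma::eig_sym(ev, V, J);
  x = ev;
  w = arma::square(V.row(0).t());
}

struct FilterObs { int interval; double dv; };

// log p(y | eta) by the kappa filter; eta enters through cl/v1 scaling
static double filter_loglik(const SubGrid &g, const arma::vec &pars,
                            const arma::vec &beta, double eta_cl,
                            double eta_v1, const arma::vec &kx,
                            const arma::vec &kw) {
  const double w = g.weight, ref = pars(P_REF_WT), fact = pars(P_FACT);
  const double sig2 = pars(P_SIGMA) * pars(P_SIGMA);
  const double pi_cl = pars(P_PI_CL);
  const double wcl0 = pars(P_THETA_CL) * std::pow(w / ref, pars(P_EXP_CL)) *
                      std::exp(eta_cl);
  const double v1 = pars(P_THETA_V1) * std::pow(w / ref, pars(P_EXP_V)) *
                    std::exp(eta_v1);
  const double v2 = v1 * fact;
  const int nk = kx.n_elem;
  const bool have_cov = beta.n_elem > 0 && g.z.n_cols > 0;

  arma::vec2 m; m.zeros();
  arma::mat22 P; P.zeros();
  double loglik = 0.0;
  arma::uword op = 0;
  while (op < g.obs_int.n_elem && g.obs_int(op) < 0) {
    // observation before any dosing: predicted concentration 0
    double fe = F_FLOOR;
    double v = sig2 * fe * fe;
    double e = g.dv(op) - 0.0;
    loglik += -0.5 * (e * e / v + std::log(2.0 * M_PI * v));
    ++op;
  }

  arma::uword k = 0;
  while (k < g.dt.n_elem) {
    // one occasion run: consecutive intervals sharing a kappa index
    const int kidx = g.kidx(k);
    arma::uword kend = k;
    while (kend < g.dt.n_elem && g.kidx(kend) == kidx) ++kend;
    const bool stochastic = (kidx >= 0) && pi_cl > 0;
    const int nn = stochastic ? nk : 1;
    // per-node states and log-weights
    std::vector<arma::vec2> ms(nn, m);
    std::vector<arma::mat22> Ps(nn, P);
    arma::vec lw(nn);
    for (int i = 0; i < nn; ++i)
      lw(i) = stochastic ? std::log(kw(i)) : 0.0;
    double block_ll = 0.0; // filled after processing
    for (arma::uword kk = k; kk < kend; ++kk) {
      double covm = have_cov ? arma::dot(g.z.row(kk).t(), beta) : 0.0;
      for (int i = 0; i < nn; ++i) {
        double kap = stochastic ? pi_cl * kx(i) : 0.0;
        double cl = wcl0 * std::exp(covm + kap);
        arma::mat22 Phi; arma::vec2 cv;
        step_matrix(cl, v1, cl * fact, v2, g.rate(kk), g.dt(kk), Phi, cv);
        ms[i] = Phi * ms[i] + cv;
        Ps[i] = Phi * Ps[i] * Phi.t();
      }
      while (op < g.obs_int.n_elem && g.obs_int(op) == (int)kk) {
        const double y = g.dv(op);
        for (int i = 0; i < nn; ++i) {
          double fm = ms[i](0) / v1;
          double fv = Ps[i](0, 0) / (v1 * v1);
          double fe = std::max(fm, F_FLOOR);
          double vy = fv * (1.0 + sig2) + sig2 * fe * fe;
          double e = y - fm;
          lw(i) += -0.5 * (e * e / vy + std::log(2.0 * M_PI * vy));
          // linear-MMSE update of the state given y
          arma::vec2 cxy = Ps[i].col(0) / v1;
          arma::vec2 K = cxy / vy;
          ms[i] += K * e;
          Ps[i] -= K * cxy.t();
          Ps[i] = 0.5 * (Ps[i] + Ps[i].t());
        }
        ++op;
      }
    }
    if (nn == 1) {
      block_ll = lw(0);
      m = ms[0];
      P = Ps[0];
    } else {
      double mx = lw.max();
      arma::vec wts = arma::exp(lw - mx);
      double sw = arma::accu(wts);
      block_ll = mx + std::log(sw);
      wts /= sw;
      m.zeros();
      for (int i = 0; i < nn; ++i) m += wts(i) * ms[i];
      P.zeros();
      for (int i = 0; i < nn; ++i) {
        arma::vec2 d = ms[i] - m;
        P += wts(i) * (Ps[i] + d * d.t());
      }
    }
    loglik += block_ll;
    k = kend;
  }
  return loglik;
}

// marginal OFV by adaptive GH over the active eta dimensions, centered at
// the joint MAP mode with the Gauss-Newton posterior covariance
static double ofv_agq(const SubGrid &g, const arma::vec &pars,
                      const arma::vec &beta, const arma::vec &bhat,
                      int n_eta = 7, int n_kap = 9) {
  arma::vec kx, kw;
  gh_rule(n_kap, kx, kw);
  const double om_cl = pars(P_OMEGA_CL), om_v1 = pars(P_OMEGA_V1);
  const int d = g.has_eta_cl + g.has_eta_v1;
  if (d == 0)
    return -2.0 * filter_loglik(g, pars, beta, 0.0, 0.0, kx, kw);

  // center and scale from the joint-mode curvature (eta block of the
  // inverse penalized-deviance Hessian), with mild inflation
  arma::vec ec(2); ec.zeros();          // (eta_cl, eta_v1) center
  arma::mat S(2, 2, arma::fill::zeros); // covariance of active dims
  {
    int j = 0;
    if (g.has_eta_cl) ec(0) = bhat.n_elem ? bhat(j++) : 0.0;
    if (g.has_eta_v1) ec(1) = bhat.n_elem ? bhat(j++) : 0.0;
    // numeric Hessian of pdev/2 over the eta dims at bhat
    const double h = 1e-3;
    arma::mat He(d, d);
    arma::vec b0 = bhat;
    double g0 = pdev_core(g, pars, beta, b0);
    for (int i = 0; i < d; ++i) {
      arma::vec bp = b0, bm = b0;
      bp(i) += h; bm(i) -= h;
      double gp = pdev_core(g, pars, beta, bp);
      double gm = pdev_core(g, pars, beta, bm);
      He(i, i) = (gp + gm - 2.0 * g0) / (h * h);
      for (int jj = 0; jj < i; ++jj) {
        arma::vec bpp = b0, bpm = b0, bmp = b0, bmm = b0;
        bpp(i) += h; bpp(jj) += h;
        bpm(i) += h; bpm(jj) -= h;
        bmp(i) -= h; bmp(jj) += h;
        bmm(i) -= h; bmm(jj) -= h;
        He(i, jj) = He(jj, i) =
          (pdev_core(g, pars, beta, bpp) - pdev_core(g, pars, beta, bpm) -
           pdev_core(g, pars, beta, bmp) + pdev_core(g, pars, beta, bmm)) /
          (4.0 * h * h);
      }
    }
    He *= 0.5; // Hessian of pdev/2 = precision of the Gaussian approx
    arma::mat Sd;
    if (!arma::inv_sympd(Sd, arma::symmatu(He))) {
      Sd = arma::inv(arma::symmatu(He) +
                     1e-6 * arma::eye(d, d));
    }
    S.submat(0, 0, d - 1, d - 1) = 1.3 * Sd; // slight inflation
  }
  arma::vec ex, ew;
  gh_rule(n_eta, ex, ew);
  arma::mat L = arma::chol(S.submat(0, 0, d - 1, d - 1), "lower");
  double ldL = arma::accu(arma::log(L.diag()));

  // iterate over the tensor grid of eta nodes
  std::vector<int> idx(d, 0);
  arma::vec terms;
  std::vector<double> tvec;
  for (;;) {
    arma::vec z(d);
    double lwgh = 0.0, z2 = 0.0;
    for (int i = 0; i < d; ++i) {
      z(i) = ex(idx[i]);
      lwgh += std::log(ew(idx[i]));
      z2 += z(i) * z(i);
    }
    arma::vec eta = L * z;
    double eta_cl = 0.0, eta_v1 = 0.0;
    int j = 0;
    if (g.has_eta_cl) { eta_cl = ec(0) + eta(j); ++j; }
    if (g.has_eta_v1) { eta_v1 = ec(1) + eta(j); }
    double ll = filter_loglik(g, pars, beta, eta_cl, eta_v1, kx, kw);
    double lp = 0.0;
    if (g.has_eta_cl)
      lp += -0.5 * (eta_cl * eta_cl / (om_cl * om_cl) +
                    std::log(2.0 * M_PI * om_cl * om_cl));
    if (g.has_eta_v1)
      lp += -0.5 * (eta_v1 * eta_v1 / (om_v1 * om_v1) +
                    std::log(2.0 * M_PI * om_v1 * om_v1));
    // AGQ weight: w_k / phi(z_k) with the |L| Jacobian
    double lt = ll + lp + lwgh + 0.5 * z2 +
                0.5 * d * std::log(2.0 * M_PI) + ldL;
    tvec.push_back(lt);
    int i = 0;
    while (i < d && ++idx[i] == (int)ex.n_elem) { idx[i] = 0; ++i; }
    if (i == d) break;
  }
  arma::vec tv(tvec);
  double mx = tv.max();
  return -2.0 * (mx + std::log(arma::accu(arma::exp(tv - mx))));
}

// [[Rcpp::export]]
NumericVector cpp_sub_ipred(List sub, NumericVector pars, NumericVector beta,
                            NumericVector b) {
  SubGrid g = unpack(sub);
  return wrap(ipred_core(g, as<arma::vec>(pars), as<arma::vec>(beta),
                         as<arma::vec>(b)));
}

// [[Rcpp::export]]
double cpp_sub_pdev(List sub, NumericVector pars, NumericVector beta,
                    NumericVector b) {
  SubGrid g = unpack(sub);
  return pdev_core(g, as<arma::vec>(pars), as<arma::vec>(beta),
                   as<arma::vec>(b));
}

// [[Rcpp::export]]
List cpp_sub_map(List sub, NumericVector pars, NumericVector beta,
                 NumericVector b0, int maxit = 200, double gtol = 1e-6) {
  SubGrid g = unpack(sub);
  return map_core(g, as<arma::vec>(pars), as<arma::vec>(beta),
                  as<arma::vec>(b0), maxit, gtol);
}

// [[Rcpp::export]]
double cpp_sub_ofv(List sub, NumericVector pars, NumericVector beta,
                   NumericVector bhat, int method = 0) {
  SubGrid g = unpack(sub);
  arma::vec p = as<arma::vec>(pars), bt = as<arma::vec>(beta),
            b = as<arma::vec>(bhat);
  if (method == 0) return ofv_foce(g, p, bt, b);
  if (method == 1) return ofv_laplace(g, p, bt, b);
  return ofv_agq(g, p, bt, b);
}

// [[Rcpp::export]]
NumericMatrix cpp_sub_jac(List sub, NumericVector pars, NumericVector beta,
                          NumericVector b) {
  SubGrid g = unpack(sub);
  return wrap(jac_core(g, as<arma::vec>(pars), as<arma::vec>(beta),
                       as<arma::vec>(b)));
}

// one marginal-objective evaluation over the whole cohort: per subject,
// find the joint MAP mode (warm-started) and add its OFV contribution
// [[Rcpp::export]]
List cpp_cohort_eval(List subs, NumericVector pars, NumericVector beta,
                     List warm, int method = 0, int maxit = 200,
                     double gtol = 1e-6) {
  const int n = subs.size();
  arma::vec p = as<arma::vec>(pars), bt = as<arma::vec>(beta);
  double total = 0.0;
  List modes(n);
  NumericVector ofv_i(n), gnorm(n);
  IntegerVector conv(n);
  for (int i = 0; i < n; ++i) {
    SubGrid g = unpack(subs[i]);
    arma::vec b0;
    if (warm.size() == n && !Rf_isNull(warm[i]))
      b0 = as<arma::vec>(warm[i]);
    List m = map_core(g, p, bt, b0, maxit, gtol);
    arma::vec bhat = as<arma::vec>(m["b"]);
    double oi = (method == 0) ? ofv_foce(g, p, bt, bhat)
              : (method == 1) ? ofv_laplace(g, p, bt, bhat)
                              : ofv_agq(g, p, bt, bhat);
    modes[i] = m["b"];
    ofv_i[i] = oi;
    gnorm[i] = as<double>(m["grad_norm"]);
    conv[i] = as<bool>(m["converged"]) ? 1 : 0;
    total += oi;
  }
  return List::create(_["ofv"] = total, _["modes"] = modes,
                      _["ofv_i"] = ofv_i, _["grad_norm"] = gnorm,
                      _["converged"] = conv);
}
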
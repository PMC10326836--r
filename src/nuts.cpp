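// Posterior and No-U-Turn sampler for the compositional Brownian model.
//
// Latent log-abundances logX = logZ + logYtilde 1' follow a matrix normal
// with mean row logZ0 and covariance C_lambda (x) R, where
// C_lambda = lambda * C + (1 - lambda) * T * I on an ultrametric tree of
// depth T.  With C = U diag(d) U' fixed, C_lambda = U diag(w) U' with
// w = lambda * d + (1 - lambda) * T.
//
// The latent logYtilde ~ N(mu_y, s2 I), with mu_y sampled and the scale
// a fixed hyperparameter, enters the likelihood linearly, so it is
// marginalised analytically:
// in the eigenbasis of C the rows of E0 = U' (logZ - 1 logZ0') are
// independent, row i distributed N(0, w_i R + s2 11').  Woodbury gives
// closed-form inverses and determinants, so one evaluation is
// O(n p + p^3).  The sampler runs over (lambda, Z0, sigma_y, R) only;
// logYtilde is recovered per posterior draw from its exact Gaussian
// conditional (see .psym_sample_logy).
//
// Unconstrained parameter vector (length 1 + (p-1) + 1 + p(p+1)/2):
//   [ a ]                logit of lambda
//   [ g_1..g_{p-1} ]     additive log-ratio of Z0 (last taxon reference)
//   [ mu_y ]             mean of the logYtilde distribution
//   [ vech(L) ]          lower Cholesky factor of R, column-major,
//                        diagonal stored on the log scale

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Rng {
  std::mt19937_64 gen;
  bool have_cached = false;
  double cached = 0.0;
  explicit Rng(std::uint64_t seed) : gen(seed) {}
  double unif() { return ((gen() >> 11) + 0.5) * (1.0 / 9007199254740992.0); }
  double norm() {
    if (have_cached) { have_cached = false; return cached; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 6.283185307179586476925286766559 * u2;
    cached = r * std::sin(a);
    have_cached = true;
    return r * std::cos(a);
  }
};

struct Model {
  mat K;          // U' logZ, n x p
  vec u1;         // U' 1_n
  vec d;          // eigenvalues of C (clamped >= 0)
  double T;       // tree depth (diagonal of C)
  int n, p, q;
  double s2;        // fixed variance of logYtilde around its mean
  double sd_loff, sd_ldiag;

  Model(const mat& logZ, const mat& U, const vec& d_, double T_,
        double sigma_y, double sd_loff_, double sd_ldiag_)
      : d(d_), T(T_), n(logZ.n_rows), p(logZ.n_cols),
        s2(sigma_y * sigma_y), sd_loff(sd_loff_), sd_ldiag(sd_ldiag_) {
    K = U.t() * logZ;
    u1 = U.t() * ones<vec>(n);
    q = 1 + (p - 1) + 1 + p * (p + 1) / 2;
  }

  // marginal log posterior and gradient
  double lp_grad(const vec& th, vec& grad) const {
    const double LOG2PI = 1.8378770664093454836;
    grad.zeros(q);

    double a = th(0);
    double lam = 1.0 / (1.0 + std::exp(-a));
    vec g = th.subvec(1, p - 1);
    double mu_y = th(p);
    vec lvec = th.subvec(p + 1, q - 1);

    vec gfull(p); gfull.subvec(0, p - 2) = g; gfull(p - 1) = 0.0;
    double mx = gfull.max();
    double lse = mx + std::log(accu(exp(gfull - mx)));
    vec logZ0 = gfull - lse;
    vec Z0 = exp(logZ0);

    mat L(p, p, fill::zeros);
    vec tdiag(p);
    {
      int k = 0;
      for (int j = 0; j < p; ++j)
        for (int i = j; i < p; ++i, ++k) {
          if (i == j) { tdiag(j) = lvec(k); L(i, j) = std::exp(lvec(k)); }
          else L(i, j) = lvec(k);
        }
    }
    if (!L.is_finite()) return -datum::inf;
    mat Linv;
    if (!inv(Linv, trimatl(L))) return -datum::inf;
    mat Rinv = Linv.t() * Linv;
    double logdetR = 2.0 * accu(tdiag);

    vec w = lam * d + (1.0 - lam) * T;
    if (w.min() <= 0) return -datum::inf;

    mat E0 = K - u1 * (logZ0.t() + mu_y);        // n x p, eigenbasis rows
    mat Ht = E0 * Rinv;                          // n x p
    vec r1 = Rinv * ones<vec>(p);
    double t1 = accu(r1);
    vec b = E0 * r1;                             // n
    vec q0 = sum(E0 % Ht, 1);                    // diag(E0 Rinv E0')
    vec cc = s2 / (w + s2 * t1);                 // Woodbury coefficients
    vec quad = (q0 - cc % square(b)) / w;

    double ll = -0.5 * n * p * LOG2PI - 0.5 * p * accu(log(w)) -
                0.5 * n * logdetR - 0.5 * accu(log1p(s2 * t1 / w)) -
                0.5 * accu(quad);

    double sp_pos = a > 0 ? a + std::log1p(std::exp(-a))
                          : std::log1p(std::exp(a));
    double sp_neg = sp_pos - a;
    double lp = ll - sp_pos - sp_neg;            // log lam + log(1 - lam)
    lp += -0.5 * mu_y * mu_y / 100.0;            // weak N(0, 10) on the mean
    {
      int k = 0;
      for (int j = 0; j < p; ++j)
        for (int i = j; i < p; ++i, ++k) {
          double sd = (i == j) ? sd_ldiag : sd_loff;
          lp += -0.5 * lvec(k) * lvec(k) / (sd * sd) - std::log(sd) -
                0.5 * LOG2PI;
        }
    }
    if (!std::isfinite(lp)) return -datum::inf;

    // ---- gradients ----
    vec dmT = d - T;
    // lambda: sum_i (d_i-T) [ -(p - c_i t1)/(2 w_i)
    //                          + (q0_i - 2 c_i b_i^2 + c_i^2 b_i^2 t1)/(2 w_i^2) ]
    vec num2 = q0 - 2.0 * cc % square(b) + square(cc) % square(b) * t1;
    double dll_dlam = accu(dmT % (-(p - cc * t1) / (2.0 * w) +
                                  num2 / (2.0 * square(w))));
    grad(0) = dll_dlam * lam * (1.0 - lam) + (1.0 - 2.0 * lam);

    // logZ0: sum_i u1_i u_i with u_i = (Ht_i' - c_i b_i r1)/w_i
    vec colgrad = Ht.t() * (u1 / w) - r1 * accu(u1 % cc % b / w);
    double csum = accu(colgrad);
    for (int k2 = 0; k2 < p - 1; ++k2)
      grad(1 + k2) = colgrad(k2) - Z0(k2) * csum;

    grad(p) = csum - mu_y / 100.0;               // mean of logYtilde

    // R: GR = -n/2 Rinv + (sum_i c_i)/2 r1 r1'
    //        + 1/2 (A1 - vcb r1' - r1 vcb' + sc r1 r1')
    mat A1 = Ht.t() * (Ht.each_col() / w);
    vec vcb = Ht.t() * (cc % b / w);
    double sc = accu(square(cc) % square(b) / w);
    mat GR = -0.5 * n * Rinv + 0.5 * accu(cc) * (r1 * r1.t()) +
             0.5 * (A1 - vcb * r1.t() - r1 * vcb.t() + sc * (r1 * r1.t()));
    mat GL = 2.0 * GR * L;
    {
      int k = 0;
      for (int j = 0; j < p; ++j)
        for (int i = j; i < p; ++i, ++k) {
          double sd = (i == j) ? sd_ldiag : sd_loff;
          if (i == j)
            grad(p + 1 + k) = GL(i, j) * L(i, j) - tdiag(j) / (sd * sd);
          else
            grad(p + 1 + k) = GL(i, j) - lvec(k) / (sd * sd);
        }
    }
    if (!grad.is_finite()) return -datum::inf;
    return lp;
  }
};

struct Hmc {
  const Model& model;
  Rng rng;
  vec inv_metric;
  double eps;
  int max_treedepth;
  double delta;

  double mu, log_eps_bar, h_bar;
  int da_count;

  double sum_accept; int n_leapfrog; bool divergent;

  Hmc(const Model& m, std::uint64_t seed, double delta_, int max_td)
      : model(m), rng(seed), inv_metric(m.q, fill::ones), eps(0.1),
        max_treedepth(max_td), delta(delta_),
        mu(0), log_eps_bar(0), h_bar(0), da_count(0),
        sum_accept(0), n_leapfrog(0), divergent(false) {}

  double kinetic(const vec& r) const {
    return 0.5 * accu(inv_metric % square(r));
  }

  bool leapfrog(vec& th, vec& r, vec& grad, double& lp, double direction) {
    double e = direction * eps;
    r += 0.5 * e * grad;
    th += e * (inv_metric % r);
    lp = model.lp_grad(th, grad);
    if (!std::isfinite(lp)) return false;
    r += 0.5 * e * grad;
    return true;
  }

  void init_stepsize(vec th, double lp0, const vec& grad0) {
    vec r(model.q);
    for (int i = 0; i < model.q; ++i)
      r(i) = rng.norm() / std::sqrt(inv_metric(i));
    double H0 = -lp0 + kinetic(r);
    vec th1 = th, r1 = r, grad1 = grad0;
    double lp1;
    if (!leapfrog(th1, r1, grad1, lp1, 1.0)) { eps = 1e-3; return; }
    double H1 = -lp1 + kinetic(r1);
    double dH = H0 - H1;
    double direction = dH > std::log(0.5) ? 1.0 : -1.0;
    for (int it = 0; it < 50; ++it) {
      eps *= std::pow(2.0, direction);
      th1 = th; r1 = r; grad1 = grad0;
      if (!leapfrog(th1, r1, grad1, lp1, 1.0)) { dH = -datum::inf; }
      else { H1 = -lp1 + kinetic(r1); dH = H0 - H1; }
      if (direction > 0 && dH <= std::log(0.5)) break;
      if (direction < 0 && dH >= std::log(0.5)) break;
    }
    eps = std::min(eps, 10.0);
    eps = std::max(eps, 1e-10);
  }

  struct Subtree {
    vec th_minus, r_minus, grad_minus;
    vec th_plus, r_plus, grad_plus;
    vec th_prop, grad_prop; double lp_prop;
    vec rho;
    double log_w;
    bool ok;
  };

  bool uturn(const vec& rho, const vec& r_minus, const vec& r_plus) const {
    return dot(rho, inv_metric % r_minus) <= 0 ||
           dot(rho, inv_metric % r_plus) <= 0;
  }

  Subtree build_tree(int depth, double direction, vec th, vec r, vec grad,
                     double H0) {
    Subtree t;
    if (depth == 0) {
      double lp;
      bool fine = leapfrog(th, r, grad, lp, direction);
      ++n_leapfrog;
      double H = fine ? -lp + kinetic(r) : datum::inf;
      double dH = H - H0;
      if (!std::isfinite(dH)) dH = datum::inf;
      if (dH > 1000.0) { divergent = true; t.ok = false; }
      else t.ok = true;
      sum_accept += dH > 0 ? std::exp(-dH) : 1.0;
      t.th_minus = t.th_plus = t.th_prop = th;
      t.r_minus = t.r_plus = r;
      t.grad_minus = t.grad_plus = t.grad_prop = grad;
      t.lp_prop = fine ? lp : -datum::inf;
      t.rho = r;
      t.log_w = -dH;
      return t;
    }
    Subtree t1 = build_tree(depth - 1, direction, th, r, grad, H0);
    if (!t1.ok) return t1;
    Subtree t2 = direction > 0
      ? build_tree(depth - 1, direction, t1.th_plus, t1.r_plus, t1.grad_plus, H0)
      : build_tree(depth - 1, direction, t1.th_minus, t1.r_minus, t1.grad_minus, H0);
    if (!t2.ok) { t1.ok = false; return t1; }
    t.ok = true;
    if (direction > 0) {
      t.th_minus = t1.th_minus; t.r_minus = t1.r_minus; t.grad_minus = t1.grad_minus;
      t.th_plus = t2.th_plus;  t.r_plus = t2.r_plus;  t.grad_plus = t2.grad_plus;
    } else {
      t.th_minus = t2.th_minus; t.r_minus = t2.r_minus; t.grad_minus = t2.grad_minus;
      t.th_plus = t1.th_plus;  t.r_plus = t1.r_plus;  t.grad_plus = t1.grad_plus;
    }
    double m12 = std::max(t1.log_w, t2.log_w);
    double lw = m12 + std::log(std::exp(t1.log_w - m12) +
                               std::exp(t2.log_w - m12));
    t.log_w = lw;
    if (std::log(rng.unif()) < t2.log_w - lw) {
      t.th_prop = t2.th_prop; t.grad_prop = t2.grad_prop; t.lp_prop = t2.lp_prop;
    } else {
      t.th_prop = t1.th_prop; t.grad_prop = t1.grad_prop; t.lp_prop = t1.lp_prop;
    }
    t.rho = t1.rho + t2.rho;
    if (uturn(t.rho, t.r_minus, t.r_plus)) t.ok = false;
    return t;
  }

  int transition(vec& th, vec& grad, double& lp) {
    vec r(model.q);
    for (int i = 0; i < model.q; ++i)
      r(i) = rng.norm() / std::sqrt(inv_metric(i));
    double H0 = -lp + kinetic(r);
    sum_accept = 0; n_leapfrog = 0; divergent = false;

    vec th_minus = th, th_plus = th, r_minus = r, r_plus = r;
    vec grad_minus = grad, grad_plus = grad;
    vec th_prop = th, grad_prop = grad;
    double lp_prop = lp;
    vec rho = r;
    double log_w = 0.0;
    int depth = 0;
    while (depth < max_treedepth) {
      double direction = rng.unif() < 0.5 ? -1.0 : 1.0;
      Subtree t = direction > 0
        ? build_tree(depth, direction, th_plus, r_plus, grad_plus, H0)
        : build_tree(depth, direction, th_minus, r_minus, grad_minus, H0);
      if (!t.ok) break;
      if (std::log(rng.unif()) < t.log_w - log_w) {
        th_prop = t.th_prop; grad_prop = t.grad_prop; lp_prop = t.lp_prop;
      }
      double mx = std::max(log_w, t.log_w);
      log_w = mx + std::log(std::exp(log_w - mx) + std::exp(t.log_w - mx));
      if (direction > 0) {
        th_plus = t.th_plus; r_plus = t.r_plus; grad_plus = t.grad_plus;
      } else {
        th_minus = t.th_minus; r_minus = t.r_minus; grad_minus = t.grad_minus;
      }
      rho += t.rho;
      ++depth;
      if (uturn(rho, r_minus, r_plus)) break;
    }
    th = th_prop; grad = grad_prop; lp = lp_prop;
    return depth;
  }

  void da_init() {
    mu = std::log(10.0 * eps);
    log_eps_bar = std::log(eps);
    h_bar = 0.0;
    da_count = 0;
  }

  void da_update() {
    const double gamma = 0.05, t0 = 10.0, kappa = 0.75;
    ++da_count;
    double accept = n_leapfrog > 0 ? sum_accept / n_leapfrog : 0.0;
    double eta = 1.0 / (da_count + t0);
    h_bar = (1.0 - eta) * h_bar + eta * (delta - accept);
    double log_eps = mu - std::sqrt((double)da_count) / gamma * h_bar;
    double x_eta = std::pow((double)da_count, -kappa);
    log_eps_bar = x_eta * log_eps + (1.0 - x_eta) * log_eps_bar;
    eps = std::max(std::exp(log_eps), 1e-5);  // guard against collapse
  }
};

}  // namespace

// [[Rcpp::export(name = ".psym_lp_grad")]]
Rcpp::List psym_lp_grad(const arma::vec& th, const arma::mat& logZ,
                        const arma::mat& U, const arma::vec& d, double T,
                        double sigma_y, double sd_loff, double sd_ldiag) {
  Model m(logZ, U, clamp(d, 1e-10, datum::inf), T, sigma_y, sd_loff,
          sd_ldiag);
  vec grad(m.q);
  double lp = m.lp_grad(th, grad);
  return Rcpp::List::create(Rcpp::Named("lp") = lp,
                            Rcpp::Named("grad") = grad);
}

// [[Rcpp::export(name = ".psym_nuts")]]
Rcpp::List psym_nuts(const arma::mat& logZ, const arma::mat& U,
                     const arma::vec& d, double T, const arma::vec& init,
                     int iter, int warmup, double adapt_delta,
                     int max_treedepth, double sigma_y, double sd_loff,
                     double sd_ldiag, double seed) {
  Model m(logZ, U, clamp(d, 1e-10, datum::inf), T, sigma_y, sd_loff,
          sd_ldiag);
  Hmc hmc(m, (std::uint64_t)seed, adapt_delta, max_treedepth);

  vec th = init, grad(m.q);
  double lp = m.lp_grad(th, grad);
  if (!std::isfinite(lp))
    Rcpp::stop("non-finite log posterior at the initial values");

  hmc.init_stepsize(th, lp, grad);
  hmc.da_init();

  // diagonal metric adaptation between an initial step-size-only buffer and
  // a terminal step-size-only buffer
  int init_buffer = std::max(5, (int)std::round(0.15 * warmup));
  int term_buffer = std::max(5, (int)std::round(0.20 * warmup));
  int adapt_end = warmup - term_buffer;
  int window_start = init_buffer;
  int window_end = init_buffer + std::max(10, (adapt_end - init_buffer) / 3);
  window_end = std::min(window_end, adapt_end);
  vec wf_mean(m.q, fill::zeros), wf_m2(m.q, fill::zeros);
  int wf_n = 0;

  int n_keep = iter - warmup;
  mat draws(n_keep, m.q);
  vec lp_keep(n_keep);
  int n_divergent = 0, n_max_depth = 0;
  double accept_sum = 0.0;

  for (int it = 0; it < iter; ++it) {
    int depth = hmc.transition(th, grad, lp);
    double accept = hmc.n_leapfrog > 0 ? hmc.sum_accept / hmc.n_leapfrog : 0.0;
    if (it >= warmup) {
      draws.row(it - warmup) = th.t();
      lp_keep(it - warmup) = lp;
      if (hmc.divergent) ++n_divergent;
      if (depth >= max_treedepth) ++n_max_depth;
      accept_sum += accept;
    } else {
      hmc.da_update();
      if (it >= window_start && it < adapt_end && warmup >= 40) {
        ++wf_n;
        vec delta1 = th - wf_mean;
        wf_mean += delta1 / wf_n;
        wf_m2 += delta1 % (th - wf_mean);
        if ((it == window_end - 1 || it == adapt_end - 1) && wf_n > 3) {
          vec v = wf_m2 / (wf_n - 1);
          hmc.inv_metric = (double)wf_n / (wf_n + 5.0) * v +
                           1e-3 * (5.0 / (wf_n + 5.0));
          wf_mean.zeros(); wf_m2.zeros(); wf_n = 0;
          window_start = it + 1;
          hmc.da_init();  // continue from the current step size
        }
      }
      if (it == warmup - 1) hmc.eps = std::exp(hmc.log_eps_bar);
    }
  }

  return Rcpp::List::create(
      Rcpp::Named("draws") = draws,
      Rcpp::Named("lp") = lp_keep,
      Rcpp::Named("stepsize") = hmc.eps,
      Rcpp::Named("n_divergent") = n_divergent,
      Rcpp::Named("n_max_treedepth") = n_max_depth,
      Rcpp::Named("mean_accept") = n_keep > 0 ? accept_sum / n_keep : NA_REAL);
}

// Exact Gaussian conditional draws of logYtilde given (lambda, Z0, R) for
// each posterior draw.  In the eigenbasis, ytilde_i | rest is univariate
// normal with precision 1/s2 + t1/w_i and mean -(b_i/w_i)/precision.
// [[Rcpp::export(name = ".psym_sample_logy")]]
arma::mat psym_sample_logy(const arma::mat& uncon_draws, const arma::mat& logZ,
                           const arma::mat& U, const arma::vec& d, double T,
                           double sigma_y, double seed) {
  int n = logZ.n_rows, p = logZ.n_cols;
  mat K = U.t() * logZ;
  vec u1 = U.t() * ones<vec>(n);
  vec dcl = clamp(d, 1e-10, datum::inf);
  double s2 = sigma_y * sigma_y;
  Rng rng((std::uint64_t)seed);
  int ndraw = uncon_draws.n_rows;
  mat out(ndraw, n);
  for (int it = 0; it < ndraw; ++it) {
    const rowvec th = uncon_draws.row(it);
    double lam = 1.0 / (1.0 + std::exp(-th(0)));
    vec gfull(p);
    for (int j = 0; j < p - 1; ++j) gfull(j) = th(1 + j);
    gfull(p - 1) = 0.0;
    double mx = gfull.max();
    double lse = mx + std::log(accu(exp(gfull - mx)));
    vec logZ0 = gfull - lse;
    double mu_y = th(p);
    mat L(p, p, fill::zeros);
    {
      int k = 0;
      for (int j = 0; j < p; ++j)
        for (int i = j; i < p; ++i, ++k)
          L(i, j) = (i == j) ? std::exp(th(p + 1 + k)) : th(p + 1 + k);
    }
    mat Linv = inv(trimatl(L));
    mat Rinv = Linv.t() * Linv;
    vec r1 = Rinv * ones<vec>(p);
    double t1 = accu(r1);
    vec w = lam * dcl + (1.0 - lam) * T;
    mat E0 = K - u1 * (logZ0.t() + mu_y);
    vec b = E0 * r1;
    vec yt(n);
    for (int i = 0; i < n; ++i) {
      double prec = 1.0 / s2 + t1 / w(i);
      double mean = -(b(i) / w(i)) / prec;
      yt(i) = mean + rng.norm() / std::sqrt(prec);
    }
    out.row(it) = mu_y + (U * yt).t();
  }
  return out;
}
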
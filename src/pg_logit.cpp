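// Polya-Gamma augmented Gibbs sampler for Bayesian logistic regression,
// plus a small ridge-stabilised IRLS fitter used by the stepwise selection
// stage. The PG(1, z) draw follows Devroye's exact alternating-series
// rejection sampler for the Jacobi J*(1, z) distribution; all randomness
// goes through R's RNG so results are reproducible under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

static const double TRUNC = 0.64;          // series/IG crossover point
static const double PISQ  = M_PI * M_PI;

// n-th coefficient of the alternating series bounding the J*(1, z) density.
static double a_coef(int n, double x) {
  double nph = n + 0.5;
  if (x > TRUNC) {
    return M_PI * nph * std::exp(-0.5 * nph * nph * PISQ * x);
  }
  return std::pow(2.0 / (M_PI * x), 1.5) * M_PI * nph *
         std::exp(-2.0 * nph * nph / x);
}

// P(sample from the truncated-exponential right piece) for the proposal.
static double mass_texpon(double z) {
  double fz = 0.125 * PISQ + 0.5 * z * z;
  double b  = std::sqrt(1.0 / TRUNC) * (TRUNC * z - 1.0);
  double a  = -std::sqrt(1.0 / TRUNC) * (TRUNC * z + 1.0);
  double x0 = std::log(fz) + fz * TRUNC;
  double xb = x0 - z + R::pnorm(b, 0.0, 1.0, 1, 1);
  double xa = x0 + z + R::pnorm(a, 0.0, 1.0, 1, 1);
  double qdivp = 4.0 / M_PI * (std::exp(xb) + std::exp(xa));
  return 1.0 / (1.0 + qdivp);
}

// Inverse-Gaussian(mu = 1/z, lambda = 1) truncated to (0, TRUNC).
static double rtigauss(double z) {
  double x = TRUNC + 1.0;
  double mu = 1.0 / z;
  if (mu > TRUNC) {
    // rejection from the z = 0 (one-sided stable) proposal
    double alpha = 0.0;
    while (unif_rand() > alpha) {
      double e1, e2;
      do {
        e1 = exp_rand();
        e2 = exp_rand();
      } while (e1 * e1 > 2.0 * e2 / TRUNC);
      x = TRUNC / ((1.0 + TRUNC * e1) * (1.0 + TRUNC * e1));
      alpha = std::exp(-0.5 * z * z * x);
    }
  } else {
    while (x > TRUNC) {
      double y = norm_rand();
      y = y * y;
      double muy = mu * y;
      x = mu + 0.5 * mu * muy - 0.5 * mu * std::sqrt(4.0 * muy + muy * muy);
      if (unif_rand() > mu / (mu + x)) x = mu * mu / x;
    }
  }
  return x;
}

// One draw from PG(1, z).
static double rpg1(double z) {
  z = 0.5 * std::fabs(z);
  double fz = 0.125 * PISQ + 0.5 * z * z;
  for (;;) {
    double x;
    if (unif_rand() < mass_texpon(z)) {
      x = TRUNC + exp_rand() / fz;
    } else {
      x = rtigauss(z);
    }
    // squeeze accept/reject on the alternating series
    double s = a_coef(0, x);
    double y = unif_rand() * s;
    int n = 0;
    for (;;) {
      ++n;
      if (n % 2 == 1) {
        s -= a_coef(n, x);
        if (y <= s) return 0.25 * x;
      } else {
        s += a_coef(n, x);
        if (y > s) break;
      }
    }
  }
}

//' @keywords internal
// [[Rcpp::export(name = ".rpg_vec")]]
Rcpp::NumericVector rpg_vec(Rcpp::NumericVector z) {
  int n = z.size();
  Rcpp::NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rpg1(z[i]);
  return out;
}

// Gibbs sampler for logit(Pr(y=1)) = X beta with beta ~ N(0, prior_var I).
// Returns the nsamp post-burn-in coefficient draws (nsamp x p).
// [[Rcpp::export(name = ".pg_gibbs")]]
arma::mat pg_gibbs(const arma::mat& X, const arma::vec& y,
                   double prior_var, int burnin, int nsamp) {
  const int n = X.n_rows, p = X.n_cols;
  arma::vec kappa = y - 0.5;
  arma::vec Xtk = X.t() * kappa;
  arma::mat P0 = arma::eye(p, p) / prior_var;
  arma::vec beta(p, arma::fill::zeros);
  arma::vec omega(n), psi(n), zdraw(p);
  arma::mat out(nsamp, p);

  for (int it = 0; it < burnin + nsamp; ++it) {
    psi = X * beta;
    for (int i = 0; i < n; ++i) omega(i) = rpg1(psi(i));
    arma::mat Vinv = X.t() * (X.each_col() % omega) + P0;
    arma::mat L = arma::chol(Vinv, "lower");
    arma::vec mu = arma::solve(arma::trimatu(L.t()),
                               arma::solve(arma::trimatl(L), Xtk));
    for (int j = 0; j < p; ++j) zdraw(j) = norm_rand();
    beta = mu + arma::solve(arma::trimatu(L.t()), zdraw);
    if (!beta.is_finite())
      Rcpp::stop("Polya-Gamma sampler produced non-finite coefficients");
    if (it >= burnin) out.row(it - burnin) = beta.t();
  }
  return out;
}

// Ridge-penalised IRLS logistic fit; the tiny default penalty only guards
// against perfect separation during stepwise subset search. Reports the
// unpenalised binomial deviance.
// [[Rcpp::export(name = ".irls_ridge")]]
Rcpp::List irls_ridge(const arma::mat& X, const arma::vec& y,
                      double lambda, int maxit, double tol) {
  const int p = X.n_cols;
  arma::vec beta(p, arma::fill::zeros);
  arma::mat R = lambda * arma::eye(p, p);
  double dev_old = R_PosInf;
  bool converged = false;
  arma::vec eta, prob, w, zres;
  for (int it = 0; it < maxit; ++it) {
    eta = X * beta;
    prob = 1.0 / (1.0 + arma::exp(-eta));
    prob = arma::clamp(prob, 1e-10, 1.0 - 1e-10);
    w = prob % (1.0 - prob);
    zres = eta + (y - prob) / w;
    arma::mat A = X.t() * (X.each_col() % w) + R;
    arma::vec b = X.t() * (w % zres);
    beta = arma::solve(A, b, arma::solve_opts::likely_sympd);
    double dev = -2.0 * arma::accu(y % arma::log(prob) +
                                   (1.0 - y) % arma::log(1.0 - prob));
    if (std::fabs(dev - dev_old) < tol * (std::fabs(dev) + 0.1)) {
      converged = true;
      dev_old = dev;
      break;
    }
    dev_old = dev;
  }
  eta = X * beta;
  prob = 1.0 / (1.0 + arma::exp(-eta));
  prob = arma::clamp(prob, 1e-10, 1.0 - 1e-10);
  double dev = -2.0 * arma::accu(y % arma::log(prob) +
                                 (1.0 - y) % arma::log(1.0 - prob));
  return Rcpp::List::create(Rcpp::Named("coefficients") = beta,
                            Rcpp::Named("deviance") = dev,
                            Rcpp::Named("fitted") = prob,
                            Rcpp::Named("converged") = converged);
}
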
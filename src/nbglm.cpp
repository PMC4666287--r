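// Batched IRLS for gene-wise negative binomial log-linear models with a
// fixed per-gene dispersion and known offsets.  All genes share one design
// matrix; weights, working responses and deviances are gene specific.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double ETA_MAX = 30.0;   // exp(30) ~ 1e13, beyond any read count
static const double MU_MIN = 1e-8;

// 2 * [loglik(saturated) - loglik(mu)] under NB with dispersion omega;
// omega = 0 is the Poisson limit.  y log y terms vanish at y = 0.
static double nb_deviance(const arma::rowvec& y, const arma::vec& mu,
                          double omega) {
  const arma::uword n = y.n_elem;
  double dev = 0.0;
  if (omega <= 0.0) {
    for (arma::uword i = 0; i < n; ++i) {
      double d = mu(i) - y(i);
      if (y(i) > 0.0) d += y(i) * std::log(y(i) / mu(i));
      dev += d;
    }
  } else {
    const double a = 1.0 / omega;
    for (arma::uword i = 0; i < n; ++i) {
      double d = 0.0;
      if (y(i) > 0.0) d += y(i) * std::log(y(i) / mu(i));
      d -= (y(i) + a) * std::log((y(i) + a) / (mu(i) + a));
      dev += d;
    }
  }
  return 2.0 * dev;
}

static arma::vec make_mu(const arma::mat& X, const arma::vec& o,
                         const arma::vec& beta) {
  arma::vec eta = o + X * beta;
  eta.clamp(-ETA_MAX, ETA_MAX);
  arma::vec mu = arma::exp(eta);
  mu.transform([](double v) { return v < MU_MIN ? MU_MIN : v; });
  return mu;
}

// [[Rcpp::export(name = ".nb_glm_batch")]]
List nb_glm_batch(const arma::mat& Y, const arma::mat& X, const arma::vec& o,
                  const arma::vec& omega, int maxit, double tol,
                  Nullable<NumericMatrix> beta_init = R_NilValue) {
  const arma::uword m = Y.n_rows, n = Y.n_cols, p = X.n_cols;
  arma::mat beta(m, p, arma::fill::zeros);
  arma::mat Mu(m, n);
  arma::vec dev(m);
  IntegerVector iters(m);
  LogicalVector conv(m);

  bool has_init = beta_init.isNotNull();
  arma::mat Binit;
  if (has_init) Binit = as<arma::mat>(beta_init.get());

  for (arma::uword g = 0; g < m; ++g) {
    const arma::rowvec y = Y.row(g);
    const double om = omega(g);
    arma::vec b(p, arma::fill::zeros);

    if (has_init) {
      b = Binit.row(g).t();
    } else {
      // one weighted least-squares step from mu0 = (y + ybar)/2 + 1/6
      const double ybar = arma::mean(y);
      arma::vec mu0 = (y.t() + ybar) / 2.0 + 1.0 / 6.0;
      arma::vec z0 = arma::log(mu0) - o;
      arma::vec w0 = mu0 / (1.0 + om * mu0);
      arma::mat Xw = X.each_col() % w0;
      bool ok = arma::solve(b, X.t() * Xw, Xw.t() * z0,
                            arma::solve_opts::likely_sympd);
      if (!ok) b.zeros();
    }

    arma::vec mu = make_mu(X, o, b);
    double devcur = nb_deviance(y, mu, om);
    bool converged = false;
    int it = 0;
    for (; it < maxit; ++it) {
      arma::vec eta_x = X * b;  // linear predictor without offset
      arma::vec w = mu / (1.0 + om * mu);
      arma::vec z = eta_x + (y.t() - mu) / mu;
      arma::mat Xw = X.each_col() % w;
      arma::vec bnew;
      bool ok = arma::solve(bnew, X.t() * Xw, Xw.t() * z,
                            arma::solve_opts::likely_sympd);
      if (!ok) break;
      arma::vec munew = make_mu(X, o, bnew);
      double devnew = nb_deviance(y, munew, om);
      // step halving if the deviance fails to decrease or is not finite
      int halves = 0;
      while ((!std::isfinite(devnew) || devnew > devcur + 1e-12) &&
             halves < 30) {
        bnew = (bnew + b) / 2.0;
        munew = make_mu(X, o, bnew);
        devnew = nb_deviance(y, munew, om);
        ++halves;
      }
      if (!std::isfinite(devnew)) break;
      const double delta = std::abs(devcur - devnew) /
                           (std::abs(devnew) + 0.1);
      b = bnew;
      mu = munew;
      devcur = devnew;
      if (delta < tol) {
        converged = true;
        ++it;
        break;
      }
    }
    beta.row(g) = b.t();
    Mu.row(g) = mu.t();
    dev(g) = devcur < 0.0 ? 0.0 : devcur;
    iters[g] = it;
    conv[g] = converged;
  }

  return List::create(_["beta"] = beta, _["mu"] = Mu, _["deviance"] = dev,
                      _["iterations"] = iters, _["converged"] = conv);
}
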
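// Compiled kernels for the skew-t mixture EM: per-component geometry,
// one combined E/CM pass over all components, and the profile
// log-likelihood in the degrees of freedom used by the v line search.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double LOG2 = std::log(2.0);

// symmetric decomposition with conditional ridge (reg scaled by trace/p)
static void decomp(const arma::mat& Sigma_in, double reg_eps,
                   arma::mat& Sigma, arma::mat& sqrtS, arma::mat& invsqrtS,
                   double& logdet) {
  int p = Sigma_in.n_rows;
  Sigma = 0.5 * (Sigma_in + Sigma_in.t());
  arma::vec ev;
  arma::mat V;
  arma::eig_sym(ev, V, Sigma);
  double mx = ev.max();
  if (ev.min() <= 0.0 || mx / std::max(ev.min(), 1e-300) > 1e10) {
    double ridge = reg_eps * arma::trace(Sigma) / p;
    if (ridge <= 0) ridge = reg_eps;
    Sigma.diag() += ridge;
    arma::eig_sym(ev, V, Sigma);
    if (ev.min() <= 0.0) stop("dispersion matrix not positive definite");
  }
  sqrtS = V * arma::diagmat(arma::sqrt(ev)) * V.t();
  invsqrtS = V * arma::diagmat(1.0 / arma::sqrt(ev)) * V.t();
  logdet = arma::accu(arma::log(ev));
}

// [[Rcpp::export]]
List cpp_geom(const arma::mat& X, const arma::mat& mu, const List& Sigma,
              const arma::mat& lam, double reg_eps) {
  int n = X.n_rows, p = X.n_cols, g = mu.n_rows;
  arma::mat D(n, g), A(n, g);
  arma::vec logdet(g);
  arma::cube SigR(p, p, g), sqrtS(p, p, g), invsqrtS(p, p, g);
  for (int j = 0; j < g; ++j) {
    arma::mat Sj = as<arma::mat>(Sigma[j]);
    arma::mat S, Sq, Si;
    double ld;
    decomp(Sj, reg_eps, S, Sq, Si, ld);
    SigR.slice(j) = S;
    sqrtS.slice(j) = Sq;
    invsqrtS.slice(j) = Si;
    logdet(j) = ld;
    arma::mat Dif = X.each_row() - mu.row(j);
    arma::mat Y = Dif * Si;          // whitened differences
    D.col(j) = arma::sum(Y % Y, 1);
    A.col(j) = Y * lam.row(j).t();
  }
  return List::create(_["d"] = D, _["A"] = A, _["logdet"] = logdet,
                      _["Sigma"] = SigR, _["sqrtS"] = sqrtS,
                      _["invsqrtS"] = invsqrtS);
}

static arma::mat log_density(const arma::mat& D, const arma::mat& A,
                             const arma::vec& logdet, double v, int p,
                             arma::mat* logcdf_out) {
  int n = D.n_rows, g = D.n_cols;
  arma::mat logf(n, g);
  double c0 = R::lgammafn((v + p) / 2.0) - R::lgammafn(v / 2.0) -
    (p / 2.0) * std::log(v * M_PI);
  for (int j = 0; j < g; ++j) {
    for (int i = 0; i < n; ++i) {
      double d = D(i, j);
      double q = std::sqrt((v + p) / (v + d)) * A(i, j);
      double lc = R::pt(q, v + p, 1, 1);
      if (logcdf_out) (*logcdf_out)(i, j) = lc;
      logf(i, j) = LOG2 + c0 - 0.5 * logdet(j) -
        ((v + p) / 2.0) * std::log1p(d / v) + lc;
    }
  }
  return logf;
}

// [[Rcpp::export]]
double cpp_profile_ll(const arma::mat& D, const arma::mat& A,
                      const arma::vec& logdet, const arma::vec& logpi,
                      double v, int p) {
  arma::mat logf = log_density(D, A, logdet, v, p, nullptr);
  logf.each_row() += logpi.t();
  arma::vec mx = arma::max(logf, 1);
  return arma::accu(mx + arma::log(arma::sum(arma::exp(logf.each_col() - mx), 1)));
}

// One E-step plus conditional M-steps for every component. Returns the
// updated parameters, the responsibilities' column sums, and the observed
// log-likelihood at the input parameters.
// [[Rcpp::export]]
List cpp_em_pass(const arma::mat& X, const arma::vec& pi_j,
                 const arma::mat& mu, const arma::mat& lam, double v,
                 const List& geom, bool fix_lambda) {
  int n = X.n_rows, p = X.n_cols, g = mu.n_rows;
  arma::mat D = as<arma::mat>(geom["d"]);
  arma::mat A = as<arma::mat>(geom["A"]);
  arma::vec logdet = as<arma::vec>(geom["logdet"]);
  arma::cube sqrtS = as<arma::cube>(geom["sqrtS"]);
  arma::cube invsqrtS_unused = as<arma::cube>(geom["invsqrtS"]);

  arma::mat logcdf(n, g);
  arma::mat logf = log_density(D, A, logdet, v, p, &logcdf);
  arma::mat lw = logf;
  for (int j = 0; j < g; ++j) lw.col(j) += std::log(pi_j(j));
  arma::vec mx = arma::max(lw, 1);
  arma::mat z = arma::exp(lw.each_col() - mx);
  arma::vec rs = arma::sum(z, 1);
  z.each_col() /= rs;
  double loglik = arma::accu(mx + arma::log(rs));
  arma::vec n_j = arma::sum(z, 0).t();

  arma::mat mu_new(g, p), lam_new(g, p);
  arma::vec pi_new = n_j / n;
  arma::cube Sigma_new(p, p, g);

  double lg_eta0 = LOG2 + (v / 2.0) * std::log(v) +
    R::lgammafn((v + p + 1) / 2.0) - R::lgammafn(v / 2.0) -
    ((p + 1) / 2.0) * std::log(M_PI);

  for (int j = 0; j < g; ++j) {
    double lamsq = arma::dot(lam.row(j), lam.row(j));
    double M2 = 1.0 / (1.0 + lamsq), M = std::sqrt(M2);
    arma::vec u(n), s2(n), s3(n);
    for (int i = 0; i < n; ++i) {
      double d = D(i, j), a = A(i, j);
      double l_num = R::pt(std::sqrt((v + p + 2) / (v + d)) * a, v + p + 2, 1, 1);
      double uh = ((v + p) / (v + d)) *
        std::exp(std::min(l_num - logcdf(i, j), 30.0));
      double log_eta = lg_eta0 - 0.5 * logdet(j) -
        ((v + p + 1) / 2.0) * std::log(v + d + a * a) - logf(i, j);
      double eta = std::exp(std::min(log_eta, 50.0));
      double mu_t = M * a;
      u(i) = uh;
      s2(i) = mu_t * uh + M * eta;
      s3(i) = mu_t * mu_t * uh + M2 + M * mu_t * eta;
    }
    arma::vec zj = z.col(j);
    arma::vec zu = zj % u, zs2 = zj % s2, zs3 = zj % s3;
    arma::rowvec delta_old(p, arma::fill::zeros);
    if (!fix_lambda)
      delta_old = (sqrtS.slice(j) * lam.row(j).t()).t() / std::sqrt(1.0 + lamsq);

    arma::rowvec wy = zu.t() * X;                       // CM-step 1: mu
    arma::rowvec mu_j = (wy - arma::accu(zs2) * delta_old) / arma::accu(zu);
    arma::mat Dif = X.each_row() - mu_j;

    arma::rowvec delta_new(p, arma::fill::zeros);       // CM-step 2: Delta
    if (!fix_lambda) delta_new = (zs2.t() * Dif) / arma::accu(zs3);

    arma::mat S1 = Dif.t() * (Dif.each_col() % zu);     // CM-step 3: Gamma
    arma::rowvec cvec = zs2.t() * Dif;
    arma::mat Gam = (S1 - delta_new.t() * cvec - cvec.t() * delta_new +
                     arma::accu(zs3) * (delta_new.t() * delta_new)) / n_j(j);
    arma::mat Sig = Gam + delta_new.t() * delta_new;
    Sig = 0.5 * (Sig + Sig.t());

    mu_new.row(j) = mu_j;
    Sigma_new.slice(j) = Sig;
    if (fix_lambda) {
      lam_new.row(j).zeros();
    } else {
      arma::vec ev;
      arma::mat V;
      arma::eig_sym(ev, V, Sig);
      ev = arma::clamp(ev, 1e-300, arma::datum::inf);
      arma::mat Si = V * arma::diagmat(1.0 / arma::sqrt(ev)) * V.t();
      arma::vec dl = Si * delta_new.t();
      double denom = std::max(1.0 - arma::dot(dl, dl), 1e-8);
      lam_new.row(j) = (dl / std::sqrt(denom)).t();
    }
  }
  return List::create(_["loglik"] = loglik, _["n_j"] = n_j,
                      _["pi"] = pi_new, _["mu"] = mu_new,
                      _["Sigma"] = Sigma_new, _["lam"] = lam_new,
                      _["z"] = z);
}
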
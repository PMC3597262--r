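#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Penalized least squares core for additive models built from small spline
// bases.  The design X carries an unpenalized intercept column plus one
// column block per smooth term; each block j has a second-derivative penalty
// S[j] scaled by its own smoothing parameter lambda[j].  GCV = n*RSS/(n-trH)^2
// drives both the per-term smoothing-parameter search (cyclic grid descent
// refined by golden section on log10 lambda) and, one level up, the threshold
// grid search of the TGAM profile.

struct Problem {
  arma::mat XtX;
  arma::vec Xty;
  double yty;
  double n;
  int J;
  std::vector<arma::uvec> cols;
  std::vector<arma::mat> S;
  std::vector<bool> pen;
};

static Problem make_problem(const arma::mat& X, const arma::vec& y,
                            const arma::ivec& block, const List& Spen) {
  Problem pr;
  pr.XtX = X.t() * X;
  pr.Xty = X.t() * y;
  pr.yty = arma::dot(y, y);
  pr.n = (double)X.n_rows;
  pr.J = Spen.size();
  pr.cols.resize(pr.J);
  pr.S.resize(pr.J);
  pr.pen.resize(pr.J);
  for (int j = 0; j < pr.J; ++j) {
    std::vector<arma::uword> idx;
    for (arma::uword c = 0; c < block.n_elem; ++c)
      if (block[c] == j + 1) idx.push_back(c);
    pr.cols[j] = arma::uvec(idx);
    pr.S[j] = as<arma::mat>(Spen[j]);
    pr.pen[j] = arma::norm(pr.S[j], "fro") > 0.0;
  }
  return pr;
}

static bool solve_pls(const Problem& pr, const arma::vec& lam,
                      arma::vec& beta, double& trH, arma::vec& edf,
                      double& rss, double& gcv, arma::mat* Ainv) {
  arma::mat A = pr.XtX;
  for (int j = 0; j < pr.J; ++j)
    if (pr.pen[j] && pr.cols[j].n_elem > 0)
      A.submat(pr.cols[j], pr.cols[j]) += lam[j] * pr.S[j];
  arma::mat Ai;
  bool ok = arma::inv_sympd(Ai, A);
  if (!ok) ok = arma::inv(Ai, A);
  if (!ok) return false;
  arma::mat F = Ai * pr.XtX;
  beta = Ai * pr.Xty;
  trH = arma::trace(F);
  edf.set_size(pr.J);
  for (int j = 0; j < pr.J; ++j) {
    double s = 0.0;
    for (arma::uword k = 0; k < pr.cols[j].n_elem; ++k)
      s += F(pr.cols[j][k], pr.cols[j][k]);
    edf[j] = s;
  }
  rss = pr.yty - 2.0 * arma::dot(beta, pr.Xty) +
        arma::dot(beta, pr.XtX * beta);
  if (rss < 0.0) rss = 0.0;
  double denom = pr.n - trH;
  gcv = (denom > 1e-8) ? pr.n * rss / (denom * denom) : R_PosInf;
  if (Ainv) *Ainv = Ai;
  return true;
}

static double gcv_only(const Problem& pr, const arma::vec& lam) {
  arma::vec beta, edf;
  double trH, rss, gcv;
  if (!solve_pls(pr, lam, beta, trH, edf, rss, gcv, nullptr)) return R_PosInf;
  return gcv;
}

// golden-section minimisation of GCV in log10(lambda[j]) over [a, b]
static double golden_term(const Problem& pr, arma::vec& loglam, int j,
                          double a, double b) {
  const double gr = 0.6180339887498949;
  double c = b - gr * (b - a), d = a + gr * (b - a);
  arma::vec lam = arma::exp10(loglam);
  auto eval = [&](double lg) {
    arma::vec ll = loglam;
    ll[j] = lg;
    return gcv_only(pr, arma::exp10(ll));
  };
  double fc = eval(c), fd = eval(d);
  for (int it = 0; it < 30 && (b - a) > 1e-4; ++it) {
    if (fc < fd) {
      b = d; d = c; fd = fc;
      c = b - gr * (b - a); fc = eval(c);
    } else {
      a = c; c = d; fc = fd;
      d = a + gr * (b - a); fd = eval(d);
    }
  }
  double best = 0.5 * (a + b);
  loglam[j] = best;
  return eval(best);
}

// cyclic per-term search; returns the final log10 lambdas
static arma::vec search_lambda(const Problem& pr, double lo, double hi,
                               int ngrid, int nsweeps) {
  arma::vec loglam(std::max(pr.J, 1), arma::fill::zeros);
  if (pr.J == 0) return loglam;
  bool any_pen = false;
  for (int j = 0; j < pr.J; ++j) {
    if (!pr.pen[j]) loglam[j] = -12.0;  // lambda irrelevant (zero penalty)
    else any_pen = true;
  }
  if (!any_pen) return loglam;
  double step = (hi - lo) / (ngrid - 1);
  for (int sweep = 0; sweep < nsweeps; ++sweep) {
    for (int j = 0; j < pr.J; ++j) {
      if (!pr.pen[j]) continue;
      double best = loglam[j], fbest = R_PosInf;
      for (int g = 0; g < ngrid; ++g) {
        double lg = lo + g * step;
        arma::vec ll = loglam;
        ll[j] = lg;
        double f = gcv_only(pr, arma::exp10(ll));
        if (f < fbest) { fbest = f; best = lg; }
      }
      loglam[j] = best;
      golden_term(pr, loglam, j,
                  std::max(lo, best - step), std::min(hi, best + step));
    }
  }
  return loglam;
}

// [[Rcpp::export]]
List pls_fit_cpp(const arma::mat& X, const arma::vec& y,
                 const arma::ivec& block, const List& Spen,
                 Nullable<NumericVector> loglambda,
                 double lo, double hi, int ngrid, int nsweeps) {
  Problem pr = make_problem(X, y, block, Spen);
  arma::vec loglam;
  if (loglambda.isNotNull()) {
    loglam = as<arma::vec>(loglambda.get());
  } else {
    loglam = search_lambda(pr, lo, hi, ngrid, nsweeps);
  }
  arma::vec lam = pr.J > 0 ? arma::vec(arma::exp10(loglam))
                           : arma::vec();
  arma::vec beta, edf;
  double trH, rss, gcv;
  arma::mat Ainv;
  if (!solve_pls(pr, lam, beta, trH, edf, rss, gcv, &Ainv))
    return List::create(_["ok"] = false);
  return List::create(
      _["ok"] = true, _["beta"] = beta, _["loglambda"] = loglam,
      _["lambda"] = lam, _["gcv"] = gcv, _["rss"] = rss, _["trh"] = trH,
      _["edf"] = edf, _["ainv"] = Ainv, _["xtx"] = pr.XtX);
}

// Threshold profile: for each candidate theta, zero out the rows of the
// low-regime columns outside the low regime (xthr <= theta) and of the
// high-regime columns inside it, then run the full smoothing-parameter
// search and record the model GCV.  col_regime: 0 shared, 1 low, 2 high.
// [[Rcpp::export]]
List tgam_profile_cpp(const arma::mat& X0, const arma::vec& y,
                      const arma::ivec& block, const arma::ivec& col_regime,
                      const List& Spen, const arma::vec& xthr,
                      const arma::vec& cand,
                      double lo, double hi, int ngrid, int nsweeps,
                      int min_low, int min_high) {
  int C = cand.n_elem;
  arma::vec gcv(C);
  gcv.fill(NA_REAL);
  arma::ivec nlow(C);
  for (int k = 0; k < C; ++k) {
    double th = cand[k];
    arma::uvec low = arma::find(xthr <= th);
    arma::uvec high = arma::find(xthr > th);
    nlow[k] = (int)low.n_elem;
    if ((int)low.n_elem < min_low || (int)high.n_elem < min_high) continue;
    arma::mat X = X0;
    for (arma::uword c = 0; c < X.n_cols; ++c) {
      if (col_regime[c] == 1) {
        for (arma::uword r = 0; r < high.n_elem; ++r) X(high[r], c) = 0.0;
      } else if (col_regime[c] == 2) {
        for (arma::uword r = 0; r < low.n_elem; ++r) X(low[r], c) = 0.0;
      }
    }
    Problem pr = make_problem(X, y, block, Spen);
    arma::vec loglam = search_lambda(pr, lo, hi, ngrid, nsweeps);
    arma::vec lam = arma::exp10(loglam);
    arma::vec beta, edf;
    double trH, rss, g;
    if (solve_pls(pr, lam, beta, trH, edf, rss, g, nullptr)) gcv[k] = g;
  }
  return List::create(_["gcv"] = gcv, _["nlow"] = nlow);
}
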
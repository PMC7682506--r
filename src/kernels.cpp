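#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Ordinary least squares via Cholesky of X'X. Returns false when the
// design is (numerically) rank deficient.
static bool ols_chol(const arma::mat& X, const arma::vec& y,
                     arma::vec& coef, double& rss, arma::mat& R) {
  arma::mat XtX = X.t() * X;
  if (!arma::chol(R, XtX)) return false;
  if (arma::rcond(XtX) < 1e-12) return false;
  arma::vec Xty = X.t() * y;
  coef = arma::solve(arma::trimatu(R),
                     arma::solve(arma::trimatl(R.t()), Xty));
  arma::vec res = y - X * coef;
  rss = arma::dot(res, res);
  return true;
}

// One draw from the noninformative-prior posterior of (beta, sigma2) in
// the normal linear model: sigma2 = RSS / chisq(n - p), then
// beta | sigma2 ~ N(betahat, sigma2 * (X'X)^-1) via the Cholesky factor.
static void posterior_draw(const arma::vec& coef, double rss,
                           const arma::mat& R, int nobs,
                           arma::vec& beta, double& sigma2) {
  const int p = coef.n_elem;
  sigma2 = rss / R::rchisq((double)(nobs - p));
  arma::vec z(p);
  for (int i = 0; i < p; ++i) z(i) = norm_rand();
  // cov(R^-1 z) = (R'R)^-1 = (X'X)^-1
  beta = coef + std::sqrt(sigma2) * arma::solve(arma::trimatu(R), z);
}

static inline int sample_row(int n) {
  int k = (int)(unif_rand() * n);
  return (k >= n) ? n - 1 : k;
}

// Proper (Bayesian) normal linear regression imputation: fit to the
// observed rows, then for each of M imputations take a fresh posterior
// draw of (beta, sigma2) and fill the missing outcomes with
// X_mis beta + N(0, sigma2) noise. Returns an n_mis x M matrix.
// [[Rcpp::export]]
arma::mat impute_normal_cpp(const arma::mat& Xobs, const arma::vec& yobs,
                            const arma::mat& Xmis, int M) {
  const int p = Xobs.n_cols;
  const int nobs = Xobs.n_rows;
  const int nmis = Xmis.n_rows;
  if (nobs < p + 2)
    stop("too few observed rows (%d) to fit the imputation model (p = %d)",
         nobs, p);
  arma::vec coef;
  double rss;
  arma::mat R;
  if (!ols_chol(Xobs, yobs, coef, rss, R))
    stop("imputation model design is singular among observed rows");
  arma::mat out(nmis, M);
  arma::vec beta;
  double sigma2;
  for (int m = 0; m < M; ++m) {
    posterior_draw(coef, rss, R, nobs, beta, sigma2);
    arma::vec mu = Xmis * beta;
    double sd = std::sqrt(sigma2);
    for (int i = 0; i < nmis; ++i)
      out(i, m) = mu(i) + sd * norm_rand();
  }
  return out;
}

// B with-replacement row resamples of (X, y); each is fitted by OLS and
// the coefficient in position `target` (1-based) is recorded. `keep`
// optionally restricts the fit to resampled rows with keep == 1 (the
// resample itself is always drawn from all n rows). Rank-deficient
// resamples are redrawn up to `max_retries` times.
// [[Rcpp::export]]
arma::vec boot_ols_cpp(const arma::mat& X, const arma::vec& y,
                       const arma::ivec& keep, int target, int B,
                       int max_retries) {
  const int n = X.n_rows;
  const int p = X.n_cols;
  const bool filt = keep.n_elem == X.n_rows;
  arma::vec est(B);
  arma::vec coef;
  double rss;
  arma::mat R;
  for (int b = 0; b < B; ++b) {
    bool ok = false;
    for (int attempt = 0; attempt <= max_retries && !ok; ++attempt) {
      arma::uvec idx(n);
      for (int i = 0; i < n; ++i) idx(i) = sample_row(n);
      arma::uvec use;
      if (filt) {
        arma::uvec sel(n);
        int k = 0;
        for (int i = 0; i < n; ++i)
          if (keep((int)idx(i)) == 1) sel(k++) = idx(i);
        if (k < p + 2) continue;
        use = sel.head(k);
      } else {
        use = idx;
      }
      arma::mat Xb = X.rows(use);
      arma::vec yb = y.elem(use);
      if (!ols_chol(Xb, yb, coef, rss, R)) continue;
      est(b) = coef(target - 1);
      ok = true;
    }
    if (!ok)
      stop("estimator failed on a bootstrap resample after %d retries",
           max_retries);
  }
  return est;
}

// Build the analysis design [1, dm[, cols], dm[, ia] * dm[, ib], ...]
// from a completed data matrix.
static arma::mat build_design(const arma::mat& dm, const arma::uvec& cols,
                              const arma::uvec& ia, const arma::uvec& ib) {
  const int n = dm.n_rows;
  const int k = cols.n_elem;
  const int q = ia.n_elem;
  arma::mat X(n, 1 + k + q);
  X.col(0).ones();
  for (int j = 0; j < k; ++j) X.col(1 + j) = dm.col(cols(j));
  for (int j = 0; j < q; ++j)
    X.col(1 + k + j) = dm.col(ia(j)) % dm.col(ib(j));
  return X;
}

// Bootstrap-then-impute estimate grid. Each of B row resamples of the
// incomplete data matrix is multiply imputed M times (fresh posterior
// draws per imputation) and analysed, giving a B x M grid of estimates
// for the target coefficient. Under J2R (`j2r = true`) the imputation
// model is fitted to observed control-arm rows (treat_col == 0) only,
// and all missing outcomes in both arms are imputed from it. All column
// and target indices are 1-based; sub_col = 0 means no subgroup filter.
// [[Rcpp::export]]
arma::mat boot_mi_grid_cpp(const arma::mat& dm, int out_col,
                           const arma::uvec& imp_pred, bool j2r,
                           int treat_col, int ana_out,
                           const arma::uvec& ana_cols,
                           const arma::uvec& inter_a,
                           const arma::uvec& inter_b, int target_pos,
                           int sub_col, double sub_val, int B, int M,
                           int max_retries) {
  const int n = dm.n_rows;
  const int oc = out_col - 1;
  const int pimp = imp_pred.n_elem + 1;
  arma::uvec ipred = imp_pred - 1;
  arma::uvec acols = ana_cols - 1;
  arma::uvec ia = inter_a, ib = inter_b;
  if (ia.n_elem > 0) { ia -= 1; ib -= 1; }
  const int pana = 1 + acols.n_elem + ia.n_elem;

  arma::mat grid(B, M);
  for (int b = 0; b < B; ++b) {
    bool ok = false;
    for (int attempt = 0; attempt <= max_retries && !ok; ++attempt) {
      arma::uvec idx(n);
      for (int i = 0; i < n; ++i) idx(i) = sample_row(n);
      arma::mat db = dm.rows(idx);
      arma::vec yout = db.col(oc);
      arma::uvec mis = arma::find_nonfinite(yout);
      arma::uvec obs = arma::find_finite(yout);
      // imputation fit rows: observed outcome, control arm only for J2R
      arma::uvec fitrows = obs;
      if (j2r) {
        arma::vec tr = db.col(treat_col - 1);
        arma::uvec sel(obs.n_elem);
        int k = 0;
        for (arma::uword i = 0; i < obs.n_elem; ++i)
          if (tr(obs(i)) == 0.0) sel(k++) = obs(i);
        if (k < pimp + 2) continue;
        fitrows = sel.head(k);
      }
      if ((int)fitrows.n_elem < pimp + 2) continue;
      arma::mat Xf(fitrows.n_elem, pimp);
      Xf.col(0).ones();
      for (arma::uword j = 0; j < ipred.n_elem; ++j)
        Xf.col(1 + j) = db.submat(fitrows, arma::uvec{ipred(j)});
      arma::vec yf = yout.elem(fitrows);
      arma::vec coef;
      double rss;
      arma::mat R;
      if (!ols_chol(Xf, yf, coef, rss, R)) continue;
      arma::mat Xm(mis.n_elem, pimp);
      if (mis.n_elem > 0) {
        Xm.col(0).ones();
        for (arma::uword j = 0; j < ipred.n_elem; ++j)
          Xm.col(1 + j) = db.submat(mis, arma::uvec{ipred(j)});
      }
      arma::rowvec ests(M);
      bool all_m_ok = true;
      for (int m = 0; m < M && all_m_ok; ++m) {
        arma::vec yc = yout;
        if (mis.n_elem > 0) {
          arma::vec beta;
          double sigma2;
          posterior_draw(coef, rss, R, fitrows.n_elem, beta, sigma2);
          arma::vec mu = Xm * beta;
          double sd = std::sqrt(sigma2);
          for (arma::uword i = 0; i < mis.n_elem; ++i)
            yc(mis(i)) = mu(i) + sd * norm_rand();
        }
        arma::mat dc = db;
        dc.col(oc) = yc;
        arma::uvec rows;
        if (sub_col > 0) {
          rows = arma::find(dc.col(sub_col - 1) == sub_val);
          if ((int)rows.n_elem < pana + 2) { all_m_ok = false; break; }
        } else {
          rows = arma::regspace<arma::uvec>(0, n - 1);
        }
        arma::mat Xa = build_design(dc.rows(rows), acols, ia, ib);
        arma::vec ya = dc.submat(rows, arma::uvec{(arma::uword)(ana_out - 1)});
        arma::vec acoef;
        double arss;
        arma::mat aR;
        if (!ols_chol(Xa, ya, acoef, arss, aR)) { all_m_ok = false; break; }
        ests(m) = acoef(target_pos - 1);
      }
      if (!all_m_ok) continue;
      grid.row(b) = ests;
      ok = true;
    }
    if (!ok)
      stop("bootstrap-then-impute failed on a resample after %d retries",
           max_retries);
  }
  return grid;
}
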
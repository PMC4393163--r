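#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Sway density curve: for every sample i, the time (s) the trajectory stays
// contiguously inside a circle of radius R (mm) centred at point i,
// truncated at the series ends.
// [[Rcpp::export(name = ".sdc_residence")]]
NumericVector sdc_residence(NumericVector ml, NumericVector ap,
                            double radius, double fs) {
  const int n = ml.size();
  const double r2 = radius * radius;
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double xi = ml[i], yi = ap[i];
    int count = 1;
    for (int j = i - 1; j >= 0; --j) {
      const double dx = ml[j] - xi, dy = ap[j] - yi;
      if (dx * dx + dy * dy > r2) break;
      ++count;
    }
    for (int j = i + 1; j < n; ++j) {
      const double dx = ml[j] - xi, dy = ap[j] - yi;
      if (dx * dx + dy * dy > r2) break;
      ++count;
    }
    out[i] = count / fs;
  }
  return out;
}

// Direct-form II transposed IIR filter with caller-supplied initial state
// (length(a) - 1 values); a[0] is assumed 1.
// [[Rcpp::export(name = ".iir_filter")]]
NumericVector iir_filter(NumericVector b, NumericVector a, NumericVector x,
                         NumericVector zi) {
  const int n = x.size(), nz = zi.size();
  std::vector<double> z(zi.begin(), zi.end());
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = b[0] * xi + (nz ? z[0] : 0.0);
    for (int j = 0; j < nz - 1; ++j) {
      z[j] = b[j + 1] * xi + z[j + 1] - a[j + 1] * yi;
    }
    if (nz) z[nz - 1] = b[nz] * xi - a[nz] * yi;
    y[i] = yi;
  }
  return y;
}

// Multi-radius variant: one backward/forward scan per sample up to the
// largest radius, recording the contiguous residence count for every radius
// (radii must be sorted increasing).  Returns an n x length(radii) matrix.
// [[Rcpp::export(name = ".sdc_residence_multi")]]
NumericMatrix sdc_residence_multi(NumericVector ml, NumericVector ap,
                                  NumericVector radii, double fs) {
  const int n = ml.size(), nr = radii.size();
  std::vector<double> r2(nr);
  for (int k = 0; k < nr; ++k) r2[k] = radii[k] * radii[k];
  const double rmax2 = r2[nr - 1];
  NumericMatrix out(n, nr);
  std::vector<int> cnt(nr);
  for (int i = 0; i < n; ++i) {
    const double xi = ml[i], yi = ap[i];
    for (int k = 0; k < nr; ++k) cnt[k] = 1;
    int kmin = 0;  // smallest radius still inside
    for (int j = i - 1; j >= 0 && kmin < nr; --j) {
      const double dx = ml[j] - xi, dy = ap[j] - yi;
      const double d2 = dx * dx + dy * dy;
      if (d2 > rmax2) break;
      while (kmin < nr && d2 > r2[kmin]) ++kmin;
      for (int k = kmin; k < nr; ++k) ++cnt[k];
    }
    kmin = 0;
    for (int j = i + 1; j < n && kmin < nr; ++j) {
      const double dx = ml[j] - xi, dy = ap[j] - yi;
      const double d2 = dx * dx + dy * dy;
      if (d2 > rmax2) break;
      while (kmin < nr && d2 > r2[kmin]) ++kmin;
      for (int k = kmin; k < nr; ++k) ++cnt[k];
    }
    for (int k = 0; k < nr; ++k) out(i, k) = cnt[k] / fs;
  }
  return out;
}

static arma::uword classify_point(const arma::rowvec &x,
                                  const arma::mat &M,
                                  const arma::mat &Sigma_inv) {
  const arma::uword p = M.n_rows;
  double best = -arma::datum::inf;
  arma::uword best_g = 0;
  for (arma::uword g = 0; g < p; ++g) {
    const arma::rowvec m = M.row(g);
    const arma::vec w = Sigma_inv * m.t();
    const double score = arma::dot(x, w) - 0.5 * arma::dot(m, w);
    if (score > best) { best = score; best_g = g; }
  }
  return best_g;
}

// Leave-one-trial-out error count for multi-class LDA with pooled
// covariance and equal priors.  cls is 0-based.  Uses rank-one downdates of
// the class mean and pooled within-class scatter for each held-out row.
// [[Rcpp::export(name = ".lda_loocv_errors")]]
int lda_loocv_errors(const arma::mat &X, const arma::ivec &cls, int nclass) {
  const arma::uword N = X.n_rows, q = X.n_cols;
  const arma::uword p = (arma::uword)nclass;
  arma::mat M(p, q, arma::fill::zeros);
  arma::vec ng(p, arma::fill::zeros);
  for (arma::uword i = 0; i < N; ++i) {
    M.row(cls[i]) += X.row(i);
    ng[cls[i]] += 1.0;
  }
  for (arma::uword g = 0; g < p; ++g) M.row(g) /= ng[g];
  arma::mat S(q, q, arma::fill::zeros);
  for (arma::uword i = 0; i < N; ++i) {
    const arma::rowvec d = X.row(i) - M.row(cls[i]);
    S += d.t() * d;
  }
  int errors = 0;
  for (arma::uword i = 0; i < N; ++i) {
    const int g = cls[i];
    const arma::rowvec xi = X.row(i);
    const double n_g = ng[g];
    arma::mat Mi = M;
    Mi.row(g) = (n_g * M.row(g) - xi) / (n_g - 1.0);
    const arma::rowvec d = xi - M.row(g);
    arma::mat Si = S - (n_g / (n_g - 1.0)) * (d.t() * d);
    arma::mat Sigma = Si / (double)(N - 1 - p);
    const double ridge = 1e-10 * arma::trace(Sigma) / (double)q;
    Sigma.diag() += ridge;
    arma::mat Sigma_inv;
    if (!arma::inv_sympd(Sigma_inv, Sigma)) {
      Sigma.diag() += 1e-6 * arma::trace(Sigma) / (double)q;
      Sigma_inv = arma::inv(Sigma);
    }
    if ((int)classify_point(xi, Mi, Sigma_inv) != g) ++errors;
  }
  return errors;
}

// Resubstitution (apparent) error count for the same classifier.
// [[Rcpp::export(name = ".lda_apparent_errors")]]
IntegerVector lda_apparent_errors(const arma::mat &X, const arma::ivec &cls,
                                  int nclass) {
  const arma::uword N = X.n_rows, q = X.n_cols;
  const arma::uword p = (arma::uword)nclass;
  arma::mat M(p, q, arma::fill::zeros);
  arma::vec ng(p, arma::fill::zeros);
  for (arma::uword i = 0; i < N; ++i) {
    M.row(cls[i]) += X.row(i);
    ng[cls[i]] += 1.0;
  }
  for (arma::uword g = 0; g < p; ++g) M.row(g) /= ng[g];
  arma::mat S(q, q, arma::fill::zeros);
  for (arma::uword i = 0; i < N; ++i) {
    const arma::rowvec d = X.row(i) - M.row(cls[i]);
    S += d.t() * d;
  }
  arma::mat Sigma = S / (double)(N - p);
  const double ridge = 1e-10 * arma::trace(Sigma) / (double)q;
  Sigma.diag() += ridge;
  arma::mat Sigma_inv;
  if (!arma::inv_sympd(Sigma_inv, Sigma)) {
    Sigma.diag() += 1e-6 * arma::trace(Sigma) / (double)q;
    Sigma_inv = arma::inv(Sigma);
  }
  IntegerVector pred(N);
  for (arma::uword i = 0; i < N; ++i) {
    pred[i] = (int)classify_point(X.row(i), M, Sigma_inv);
  }
  return pred;
}
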
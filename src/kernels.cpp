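#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Mid-ranks (average ranks for ties), 1-based values.
static arma::vec midranks(const arma::vec& x) {
  const int n = x.n_elem;
  arma::uvec ord = arma::stable_sort_index(x);
  arma::vec r(n);
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && x(ord(j + 1)) == x(ord(i))) ++j;
    const double avg = 0.5 * (i + j) + 1.0;
    for (int k = i; k <= j; ++k) r(ord(k)) = avg;
    i = j + 1;
  }
  return r;
}

static double pearson_stat(const arma::vec& x, const arma::vec& y) {
  const double sx = arma::stddev(x), sy = arma::stddev(y);
  if (sx <= 0.0 || sy <= 0.0 || !std::isfinite(sx) || !std::isfinite(sy))
    return NA_REAL;
  arma::mat r = arma::cor(x, y);
  return r(0, 0);
}

static double spearman_stat(const arma::vec& x, const arma::vec& y) {
  return pearson_stat(midranks(x), midranks(y));
}

static double bray_stat(const arma::vec& x, const arma::vec& y) {
  const double tot = arma::accu(x) + arma::accu(y);
  if (tot <= 0.0) return NA_REAL;
  return 1.0 - 2.0 * arma::accu(arma::min(x, y)) / tot;
}

// Equal-frequency binning on mid-ranks; constant vectors occupy one bin.
static arma::ivec ef_bins(const arma::vec& x, const int bins) {
  const int n = x.n_elem;
  arma::vec r = midranks(x);
  arma::ivec b(n);
  for (int i = 0; i < n; ++i) {
    int bi = (int)std::floor((r(i) - 0.5) * bins / n);
    if (bi < 0) bi = 0;
    if (bi >= bins) bi = bins - 1;
    b(i) = bi;
  }
  return b;
}

// Plug-in mutual information in nats over the bins x bins contingency table.
static double mi_stat(const arma::vec& x, const arma::vec& y, const int bins) {
  const int n = x.n_elem;
  arma::ivec bx = ef_bins(x, bins), by = ef_bins(y, bins);
  arma::mat joint(bins, bins, arma::fill::zeros);
  for (int i = 0; i < n; ++i) joint(bx(i), by(i)) += 1.0;
  joint /= n;
  arma::vec px = arma::sum(joint, 1), py = arma::sum(joint, 0).t();
  double mi = 0.0;
  for (int a = 0; a < bins; ++a)
    for (int b = 0; b < bins; ++b)
      if (joint(a, b) > 0.0)
        mi += joint(a, b) * std::log(joint(a, b) / (px(a) * py(b)));
  return mi > 0.0 ? mi : 0.0;
}

// measure codes: 0 = bray_curtis, 1 = pearson, 2 = spearman, 3 = mi
static double score_one(const arma::vec& x, const arma::vec& y,
                        const int measure, const int bins) {
  switch (measure) {
    case 0: return bray_stat(x, y);
    case 1: return pearson_stat(x, y);
    case 2: return spearman_stat(x, y);
    case 3: return mi_stat(x, y, bins);
    default: stop("unknown measure code");
  }
  return NA_REAL;
}

// [[Rcpp::export]]
double cpp_measure(const arma::vec& x, const arma::vec& y,
                   const int measure, const int bins) {
  return score_one(x, y, measure, bins);
}

// ReBoot null for one pair: permute x across samples, re-close each sample
// (rows of the source table sum to 1), recompute the measure on the
// renormalized pair. perms is n x P of 1-based indices.
// [[Rcpp::export]]
arma::vec cpp_reboot_null(const arma::vec& x, const arma::vec& y,
                          const arma::imat& perms, const int measure,
                          const int bins) {
  const int n = x.n_elem, P = perms.n_cols;
  arma::vec out(P);
  arma::vec xp(n), denom(n);
  for (int k = 0; k < P; ++k) {
    for (int i = 0; i < n; ++i) xp(i) = x(perms(i, k) - 1);
    denom = 1.0 - x + xp;
    out(k) = score_one(xp / denom, y / denom, measure, bins);
  }
  return out;
}

// Scores on row-subsets (bootstrap resamples); idx is n x B, 1-based.
// [[Rcpp::export]]
arma::vec cpp_subset_scores(const arma::vec& x, const arma::vec& y,
                            const arma::imat& idx, const int measure,
                            const int bins) {
  const int n = idx.n_rows, B = idx.n_cols;
  arma::vec out(B), xs(n), ys(n);
  for (int k = 0; k < B; ++k) {
    for (int i = 0; i < n; ++i) {
      xs(i) = x(idx(i, k) - 1);
      ys(i) = y(idx(i, k) - 1);
    }
    out(k) = score_one(xs, ys, measure, bins);
  }
  return out;
}

// Scores of (x, y[perm]) for shuffled-response nulls; perms n x P, 1-based.
// [[Rcpp::export]]
arma::vec cpp_permute_y_scores(const arma::vec& x, const arma::vec& y,
                               const arma::imat& perms, const int measure,
                               const int bins) {
  const int n = y.n_elem, P = perms.n_cols;
  arma::vec out(P), yp(n);
  for (int k = 0; k < P; ++k) {
    for (int i = 0; i < n; ++i) yp(i) = y(perms(i, k) - 1);
    out(k) = score_one(x, yp, measure, bins);
  }
  return out;
}

// Componentwise L2 boosting of a linear model: X and y must arrive
// column-standardized (mean 0); columns with zero variance must be all-zero.
// Returns coefficients on the standardized scale.
static arma::vec gblm_core(const arma::mat& X, const arma::vec& y,
                           const double nu, const int M) {
  const int p = X.n_cols;
  arma::vec beta(p, arma::fill::zeros);
  arma::vec ss(p);
  for (int j = 0; j < p; ++j) ss(j) = arma::dot(X.col(j), X.col(j));
  arma::vec r = y;
  for (int m = 0; m < M; ++m) {
    arma::vec c = X.t() * r;
    int best = -1;
    double bestval = 0.0;
    for (int j = 0; j < p; ++j) {
      if (ss(j) <= 0.0) continue;
      const double v = std::fabs(c(j)) / std::sqrt(ss(j));
      if (v > bestval) { bestval = v; best = j; }
    }
    if (best < 0 || bestval == 0.0) break;
    const double slope = c(best) / ss(best);
    beta(best) += nu * slope;
    r -= (nu * slope) * X.col(best);
  }
  return beta;
}

// Center and scale columns to unit sample SD; constant columns -> all zero.
static arma::mat std_cols(const arma::mat& A) {
  arma::mat Z = A;
  for (arma::uword j = 0; j < Z.n_cols; ++j) {
    const double mu = arma::mean(Z.col(j));
    const double sd = arma::stddev(Z.col(j));
    if (sd > 0.0) Z.col(j) = (Z.col(j) - mu) / sd;
    else Z.col(j).zeros();
  }
  return Z;
}

// [[Rcpp::export]]
arma::vec cpp_gblm(const arma::mat& X, const arma::vec& y,
                   const double nu, const int M) {
  return gblm_core(std_cols(X), std_cols(arma::mat(y)).col(0), nu, M);
}

// Coefficient of predictor `pred` when boosting target `target` on all other
// columns of the (already standardized) table Z. 0-based indices.
static double coef_of(const arma::mat& Z, const int target, const int pred,
                      const double nu, const int M) {
  const int p = Z.n_cols;
  arma::mat X(Z.n_rows, p - 1);
  int col = 0, pred_pos = -1;
  for (int j = 0; j < p; ++j) {
    if (j == target) continue;
    if (j == pred) pred_pos = col;
    X.col(col++) = Z.col(j);
  }
  arma::vec beta = gblm_core(X, Z.col(target), nu, M);
  return beta(pred_pos);
}

static double gblm_pair_score(const arma::mat& T, const int i, const int j,
                              const double nu, const int M) {
  arma::mat Z = std_cols(T);
  return 0.5 * (coef_of(Z, i, j, nu, M) + coef_of(Z, j, i, nu, M));
}

// Symmetrized pairwise GBLM score for columns i, j (1-based) of a table.
// [[Rcpp::export]]
double cpp_gblm_pair(const arma::mat& T, const int i, const int j,
                     const double nu, const int M) {
  return gblm_pair_score(T, i - 1, j - 1, nu, M);
}

// Full coefficient matrix: entry (k, t) is the boosting coefficient of
// predictor k in the fit for target t (diagonal 0).
// [[Rcpp::export]]
arma::mat cpp_gblm_all(const arma::mat& T, const double nu, const int M) {
  const int p = T.n_cols;
  arma::mat Z = std_cols(T);
  arma::mat C(p, p, arma::fill::zeros);
  for (int t = 0; t < p; ++t) {
    arma::mat X(Z.n_rows, p - 1);
    int col = 0;
    for (int j = 0; j < p; ++j) if (j != t) X.col(col++) = Z.col(j);
    arma::vec beta = gblm_core(X, Z.col(t), nu, M);
    col = 0;
    for (int j = 0; j < p; ++j) if (j != t) C(j, t) = beta(col++);
  }
  return C;
}

// ReBoot null for the GBLM pair score: permute column i of the relative
// table, re-close each row, refit targets i and j. perms n x P, 1-based.
// [[Rcpp::export]]
arma::vec cpp_gblm_reboot(const arma::mat& Trel, const int i, const int j,
                          const arma::imat& perms, const double nu,
                          const int M) {
  const int n = Trel.n_rows, P = perms.n_cols;
  arma::vec out(P);
  for (int k = 0; k < P; ++k) {
    arma::mat Tp = Trel;
    for (int s = 0; s < n; ++s) Tp(s, i - 1) = Trel(perms(s, k) - 1, i - 1);
    arma::vec rs = arma::sum(Tp, 1);
    Tp.each_col() /= rs;
    out(k) = gblm_pair_score(Tp, i - 1, j - 1, nu, M);
  }
  return out;
}

// Bootstrap of the GBLM pair score over row resamples; idx n x B, 1-based.
// [[Rcpp::export]]
arma::vec cpp_gblm_boot(const arma::mat& Trel, const int i, const int j,
                        const arma::imat& idx, const double nu, const int M) {
  const int n = idx.n_rows, B = idx.n_cols;
  arma::vec out(B);
  for (int k = 0; k < B; ++k) {
    arma::mat Tb(n, Trel.n_cols);
    for (int s = 0; s < n; ++s) Tb.row(s) = Trel.row(idx(s, k) - 1);
    out(k) = gblm_pair_score(Tb, i - 1, j - 1, nu, M);
  }
  return out;
}
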
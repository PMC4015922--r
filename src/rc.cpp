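#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// The ensemble evaluates ordinary least squares of P on k motif columns plus
// an intercept for a huge number of subsets. Precomputing the full Gram
// matrix G = X'X and g = X'P for X = [1 | R] once makes each subset an
// O((k+1)^3) solve on a submatrix instead of an O(n k^2) regression, which
// is what makes 1e6 iterations practical.
struct rc_state {
  arma::mat G;    // (m+1) x (m+1)
  arma::vec g;    // (m+1)
  double yy;      // P'P
};

static rc_state make_state(const arma::mat &R, const arma::vec &P) {
  arma::uword n = R.n_rows, m = R.n_cols;
  arma::mat X(n, m + 1);
  X.col(0).ones();
  X.cols(1, m) = R;
  rc_state st;
  st.G = X.t() * X;
  st.g = X.t() * P;
  st.yy = arma::dot(P, P);
  return st;
}

// Residual sum of squares of the subset regression (intercept + the motif
// columns listed in `subset`, 0-based). Numerically singular (exactly
// collinear) subsets fall back to a tiny ridge so no iteration aborts.
static double subset_sse(const rc_state &st, const arma::uvec &idx) {
  arma::mat A = st.G.submat(idx, idx);
  arma::vec rhs = st.g.elem(idx);
  arma::vec beta;
  bool ok = arma::solve(beta, A, rhs, arma::solve_opts::likely_sympd +
                                      arma::solve_opts::no_approx);
  if (!ok) {
    arma::mat Ar = A;
    Ar.diag() += 1e-8;
    arma::solve(beta, Ar, rhs);
  }
  // E = P'P - 2 b'g + b'A b (exact also under the ridge fallback)
  double E = st.yy - 2.0 * arma::dot(beta, rhs) +
             arma::dot(beta, A * beta);
  return E > 0.0 ? E : 0.0;
}

// Random-subset regulatory-capacity ensemble. Each iteration samples k
// distinct motif columns uniformly (R's RNG, so set.seed() governs it),
// fits OLS with intercept, and adds 1 / max(E, eps_guard)^alpha to each
// sampled motif's RC. Returns RC and per-motif selection counts.
// [[Rcpp::export]]
List rc_sample_cpp(const arma::mat &R, const arma::vec &P, int k,
                   double n_iter, double alpha, double eps_guard) {
  arma::uword m = R.n_cols;
  rc_state st = make_state(R, P);
  arma::vec rc(m, arma::fill::zeros);
  arma::vec cnt(m, arma::fill::zeros);
  std::vector<arma::uword> pool(m);
  arma::uvec idx(k + 1);
  idx[0] = 0;  // intercept
  for (double it = 0; it < n_iter; ++it) {
    for (arma::uword j = 0; j < m; ++j) pool[j] = j;
    for (int j = 0; j < k; ++j) {   // partial Fisher-Yates
      int r = j + (int)(unif_rand() * (m - j));
      if (r >= (int)m) r = (int)m - 1;
      std::swap(pool[j], pool[r]);
      idx[j + 1] = pool[j] + 1;
    }
    double E = subset_sse(st, idx);
    double contrib = std::pow(1.0 / std::max(E, eps_guard), alpha);
    for (int j = 0; j < k; ++j) {
      rc[idx[j + 1] - 1] += contrib;
      cnt[idx[j + 1] - 1] += 1.0;
    }
  }
  return List::create(_["rc"] = rc, _["count"] = cnt);
}

// Exhaustive-mode RC: evaluates the caller-supplied subsets (1-based motif
// index matrix, one subset per column) exactly once each.
// [[Rcpp::export]]
List rc_enumerate_cpp(const arma::mat &R, const arma::vec &P,
                      const arma::umat &subsets, double alpha,
                      double eps_guard) {
  arma::uword m = R.n_cols, k = subsets.n_rows;
  rc_state st = make_state(R, P);
  arma::vec rc(m, arma::fill::zeros);
  arma::vec cnt(m, arma::fill::zeros);
  arma::uvec idx(k + 1);
  idx[0] = 0;
  for (arma::uword c = 0; c < subsets.n_cols; ++c) {
    for (arma::uword j = 0; j < k; ++j) idx[j + 1] = subsets(j, c);
    double E = subset_sse(st, idx);
    double contrib = std::pow(1.0 / std::max(E, eps_guard), alpha);
    for (arma::uword j = 0; j < k; ++j) {
      rc[idx[j + 1] - 1] += contrib;
      cnt[idx[j + 1] - 1] += 1.0;
    }
  }
  return List::create(_["rc"] = rc, _["count"] = cnt);
}
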
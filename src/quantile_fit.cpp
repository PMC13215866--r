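// Quantile regression by vertex exchange on the check-loss objective.
//
// A minimiser of sum_i rho_tau(y_i - x_i'b) can be taken to interpolate p
// observations when the design has full column rank (a vertex of the
// piecewise-linear objective). Starting from such a basic solution we
// repeatedly test the one-sided directional derivatives along the p basis
// directions and, while one is negative, perform the exact piecewise-linear
// line search (a weighted-quantile step) and swap the basis row whose
// residual reaches zero. Finite termination up to degeneracy; an iteration
// cap guards against cycling on tied data.

#include <RcppArmadillo.h>
#include <algorithm>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static double check_loss(const arma::vec& r, double tau) {
  double s = 0.0;
  for (arma::uword i = 0; i < r.n_elem; ++i)
    s += r(i) * (tau - (r(i) < 0.0 ? 1.0 : 0.0));
  return s;
}

// slope of rho_tau(r - t*a) at t -> 0+ for a single non-basis row; residuals
// within ztol of zero (e.g. duplicated rows under bootstrap resampling) are
// treated as exact zeros, whose one-sided derivative is non-negative either
// way -- otherwise their ~1e-17 residuals produce zero-length exchange steps
// and the algorithm cycles
static inline double dir_slope(double r, double a, double tau, double ztol) {
  if (r > ztol) return -a * tau;
  if (r < -ztol) return a * (1.0 - tau);
  return (a > 0.0) ? a * (1.0 - tau) : -a * tau;
}

// Greedy selection of p linearly independent rows, preferring rows with
// small |resid0| so the start is near the OLS fit.
static arma::uvec initial_basis(const arma::mat& X, const arma::vec& resid0) {
  const arma::uword n = X.n_rows, p = X.n_cols;
  arma::uvec ord = arma::sort_index(arma::abs(resid0));
  std::vector<arma::uword> keep;
  arma::mat M;
  for (arma::uword k = 0; k < n && keep.size() < p; ++k) {
    arma::mat Mc = arma::join_cols(M, X.row(ord(k)));
    if (arma::rank(Mc) == Mc.n_rows) {
      M = Mc;
      keep.push_back(ord(k));
    }
  }
  if (keep.size() < p) stop("design matrix is rank deficient");
  return arma::uvec(keep);
}

struct QrResult {
  arma::vec coef;
  double objective;
  bool converged;
  int iterations;
};

static QrResult qr_fit_core(const arma::mat& X, const arma::vec& y,
                            double tau) {
  const arma::uword n = X.n_rows, p = X.n_cols;
  if (n < p) stop("fewer observations than coefficients");

  // OLS start (ridge fallback for ill-conditioned X'X)
  arma::mat XtX = X.t() * X;
  arma::vec b0;
  if (!arma::solve(b0, XtX, X.t() * y, arma::solve_opts::no_approx)) {
    b0 = arma::solve(XtX + 1e-8 * arma::eye(p, p), X.t() * y);
  }
  arma::uvec B = initial_basis(X, y - X * b0);

  const double tol = 1e-10;
  const double ztol = 1e-9 * (1.0 + arma::mean(arma::abs(y)));
  const int max_iter = 100 * static_cast<int>(n + p);
  arma::vec b(p, arma::fill::zeros);
  bool converged = false;
  int iter = 0;

  std::vector<bool> in_basis(n, false);

  for (iter = 0; iter < max_iter; ++iter) {
    arma::mat Xb = X.rows(B);
    arma::mat Xbi;
    if (!arma::inv(Xbi, Xb)) stop("singular basis encountered");
    b = Xbi * y(B);
    arma::vec r = y - X * b;
    r(B).zeros(); // exact zeros at basis rows

    std::fill(in_basis.begin(), in_basis.end(), false);
    for (arma::uword j = 0; j < p; ++j) in_basis[B(j)] = true;

    // directional derivatives along +/- each basis direction
    double best = -tol;
    arma::uword best_j = 0;
    double best_s = 0.0;
    arma::mat A = X * Xbi; // column j = a-values for direction j
    for (arma::uword j = 0; j < p; ++j) {
      double dplus = 1.0 - tau, dminus = tau;
      for (arma::uword i = 0; i < n; ++i) {
        if (in_basis[i]) continue;
        double a = A(i, j);
        if (a == 0.0) continue;
        dplus += dir_slope(r(i), a, tau, ztol);
        dminus += dir_slope(r(i), -a, tau, ztol);
      }
      if (dplus < best) { best = dplus; best_j = j; best_s = 1.0; }
      if (dminus < best) { best = dminus; best_j = j; best_s = -1.0; }
    }
    if (best_s == 0.0) { converged = true; break; }

    // piecewise-linear line search along b + t * s * d
    double g = best;
    std::vector<std::pair<double, arma::uword>> cross;
    cross.reserve(n);
    for (arma::uword i = 0; i < n; ++i) {
      if (in_basis[i]) continue;
      double sa = best_s * A(i, best_j);
      if (sa == 0.0 || std::fabs(r(i)) <= ztol) continue;
      double t = r(i) / sa;
      if (t > 0.0) cross.push_back(std::make_pair(t, i));
    }
    if (cross.empty()) stop("unbounded quantile objective (check design)");
    std::sort(cross.begin(), cross.end());
    arma::uword enter = cross.back().second;
    for (std::size_t k = 0; k < cross.size(); ++k) {
      g += std::fabs(A(cross[k].second, best_j));
      if (g >= 0.0) { enter = cross[k].second; break; }
    }
    B(best_j) = enter;
  }

  QrResult out;
  out.coef = b;
  out.objective = check_loss(y - X * b, tau);
  out.converged = converged;
  out.iterations = iter;
  return out;
}

// [[Rcpp::export(name = ".qr_fit_cpp")]]
List qr_fit_cpp(const arma::mat& X, const arma::vec& y, double tau) {
  QrResult res = qr_fit_core(X, y, tau);
  return List::create(_["coefficients"] = res.coef,
                      _["objective"] = res.objective,
                      _["converged"] = res.converged,
                      _["iterations"] = res.iterations);
}

// Fit every tau on every bootstrap resample. idx is n x reps, 0-based row
// indices drawn in R so that seeding stays under R's RNG.
// [[Rcpp::export(name = ".qr_boot_cpp")]]
arma::cube qr_boot_cpp(const arma::mat& X, const arma::vec& y,
                       const arma::vec& taus, const arma::umat& idx) {
  const arma::uword p = X.n_cols, reps = idx.n_cols, k = taus.n_elem;
  arma::cube out(p, k, reps);
  for (arma::uword r = 0; r < reps; ++r) {
    arma::mat Xb = X.rows(idx.col(r));
    arma::vec yb = y(idx.col(r));
    for (arma::uword t = 0; t < k; ++t) {
      // a resample can lose a rare indicator entirely and go rank deficient;
      // flag it with NaN so callers can drop the replicate
      try {
        out.slice(r).col(t) = qr_fit_core(Xb, yb, taus(t)).coef;
      } catch (const std::exception&) {
        out.slice(r).col(t).fill(arma::datum::nan);
      }
    }
  }
  return out;
}
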
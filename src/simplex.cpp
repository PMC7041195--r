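// Bounded-variable two-phase primal simplex, dense.
//
// Solves  min c'x  s.t.  A x = b,  l <= x <= u  (entries of l/u may be +-Inf).
// Inequality rows are converted to equalities by slack columns on the R side.
// The basis matrix is refactorised at every iteration (problems here are
// small: tens of rows), which trades speed for numerical transparency.
// Dantzig pricing with a switch to Bland's rule after 2(n+m) iterations
// guards against cycling on degenerate vertices.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

const int ST_LOWER = 0;   // nonbasic at lower bound
const int ST_UPPER = 1;   // nonbasic at upper bound
const int ST_FREE  = 2;   // nonbasic free variable, held at 0
const int ST_BASIC = 3;

const double DTOL = 1e-9;   // reduced-cost tolerance
const double PTOL = 1e-10;  // pivot magnitude tolerance

struct SimplexResult {
  int status;       // 0 optimal, 1 infeasible, 2 unbounded, 3 iteration limit
  vec x;
  double obj;
};

// Run the simplex on the current basis/status to optimality of cost c.
// Returns 0 optimal, 2 unbounded, 3 iteration limit.
int simplex_core(const mat& A, const vec& b, const vec& c,
                 const vec& l, const vec& u,
                 uvec& basis, ivec& stat, vec& x, int maxit) {
  const uword m = A.n_rows, n = A.n_cols;
  const int bland_after = 2 * (int)(n + m) + 20;

  for (int iter = 0; iter < maxit; ++iter) {
    // nonbasic values
    for (uword j = 0; j < n; ++j) {
      if (stat[j] == ST_LOWER) x[j] = l[j];
      else if (stat[j] == ST_UPPER) x[j] = u[j];
      else if (stat[j] == ST_FREE) x[j] = 0.0;
    }
    mat B = A.cols(basis);
    vec rhs = b;
    for (uword j = 0; j < n; ++j)
      if (stat[j] != ST_BASIC && x[j] != 0.0) rhs -= A.col(j) * x[j];
    vec xB;
    if (!solve(xB, B, rhs, solve_opts::no_approx)) return 3;
    for (uword i = 0; i < m; ++i) x[basis[i]] = xB[i];

    // duals and reduced costs
    vec cB(m);
    for (uword i = 0; i < m; ++i) cB[i] = c[basis[i]];
    vec y;
    if (!solve(y, B.t(), cB, solve_opts::no_approx)) return 3;

    // entering variable
    const bool bland = iter > bland_after;
    sword q = -1;
    int qdir = 0;
    double best = DTOL;
    for (uword j = 0; j < n; ++j) {
      if (stat[j] == ST_BASIC) continue;
      double dj = c[j] - dot(y, A.col(j));
      int dir = 0;
      double score = 0.0;
      if (stat[j] == ST_LOWER && dj < -DTOL) { dir = +1; score = -dj; }
      else if (stat[j] == ST_UPPER && dj > DTOL) { dir = -1; score = dj; }
      else if (stat[j] == ST_FREE && std::fabs(dj) > DTOL) {
        dir = dj < 0 ? +1 : -1; score = std::fabs(dj);
      }
      if (dir != 0) {
        if (bland) { q = j; qdir = dir; break; }
        if (score > best) { best = score; q = j; qdir = dir; }
      }
    }
    if (q < 0) return 0;  // optimal

    // ratio test: entering moves by t*qdir, basics move by -w*t*qdir
    vec w;
    if (!solve(w, B, A.col((uword)q), solve_opts::no_approx)) return 3;
    double tmax = datum::inf;
    sword leave = -1;      // position in basis; -1 = bound flip of q
    int leave_to = ST_LOWER;
    if (std::isfinite(l[q]) && std::isfinite(u[q])) tmax = u[q] - l[q];
    for (uword i = 0; i < m; ++i) {
      double delta = -w[i] * qdir;  // d x_{basis[i]} / dt
      double t = datum::inf;
      int to = ST_LOWER;
      if (delta < -PTOL) {
        if (std::isfinite(l[basis[i]]))
          t = (x[basis[i]] - l[basis[i]]) / (-delta);
        to = ST_LOWER;
      } else if (delta > PTOL) {
        if (std::isfinite(u[basis[i]]))
          t = (u[basis[i]] - x[basis[i]]) / delta;
        to = ST_UPPER;
      } else continue;
      if (t < -1e-11) t = 0.0;
      if (t < tmax - 1e-12 ||
          (t < tmax + 1e-12 && leave >= 0 && basis[i] < basis[(uword)leave])) {
        tmax = t; leave = i; leave_to = to;
      }
    }
    if (!std::isfinite(tmax)) return 2;  // unbounded direction
    if (tmax < 0) tmax = 0;

    if (leave < 0) {
      // entering variable flips bound
      stat[q] = (qdir > 0) ? ST_UPPER : ST_LOWER;
    } else {
      uword out = basis[(uword)leave];
      stat[out] = leave_to;
      basis[(uword)leave] = (uword)q;
      stat[q] = ST_BASIC;
    }
  }
  return 3;
}

}  // namespace

// [[Rcpp::export(name = ".cppSolveLP")]]
Rcpp::List cppSolveLP(const arma::mat& A, const arma::vec& b,
                      const arma::vec& c, const arma::vec& l,
                      const arma::vec& u, int maxit = 20000) {
  const uword m = A.n_rows, n = A.n_cols;

  // ---- phase 1: artificial columns -------------------------------------
  mat A1(m, n + m, fill::zeros);
  A1.head_cols(n) = A;
  vec l1(n + m), u1(n + m), c1(n + m, fill::zeros), x(n + m, fill::zeros);
  l1.head(n) = l; u1.head(n) = u;
  ivec stat(n + m);
  for (uword j = 0; j < n; ++j) {
    if (std::isfinite(l[j])) stat[j] = ST_LOWER;
    else if (std::isfinite(u[j])) stat[j] = ST_UPPER;
    else stat[j] = ST_FREE;
    x[j] = (stat[j] == ST_LOWER) ? l[j] : (stat[j] == ST_UPPER ? u[j] : 0.0);
  }
  vec r = b - A * x.head(n);
  uvec basis(m);
  for (uword i = 0; i < m; ++i) {
    A1(i, n + i) = (r[i] >= 0) ? 1.0 : -1.0;
    l1[n + i] = 0.0; u1[n + i] = datum::inf;
    c1[n + i] = 1.0;
    stat[n + i] = ST_BASIC;
    basis[i] = n + i;
  }
  int st = simplex_core(A1, b, c1, l1, u1, basis, stat, x, maxit);
  if (st == 3) return Rcpp::List::create(Rcpp::Named("status") = 3);
  double infeas = 0.0;
  for (uword i = 0; i < m; ++i) infeas += x[n + i];
  if (st == 2 || infeas > 1e-7)
    return Rcpp::List::create(Rcpp::Named("status") = 1);

  // ---- phase 2: pin artificials at zero, restore true costs ------------
  for (uword i = 0; i < m; ++i) { u1[n + i] = 0.0; c1[n + i] = 0.0; }
  vec c2(n + m, fill::zeros);
  c2.head(n) = c;
  st = simplex_core(A1, b, c2, l1, u1, basis, stat, x, maxit);
  if (st != 0) return Rcpp::List::create(Rcpp::Named("status") = st);

  vec xout = x.head(n);
  return Rcpp::List::create(
      Rcpp::Named("status") = 0,
      Rcpp::Named("x") = xout,
      Rcpp::Named("objval") = dot(c, xout));
}
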
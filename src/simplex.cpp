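// Dense two-phase primal simplex for the FBA / gap-filling LPs.
//
// Solves   min  c'x   s.t.  Aeq x = beq,  Aub x <= bub,  x >= 0
// (maximisation handled by the caller negating c).  Problems here are
// small (a few hundred rows/columns) so a dense tableau is adequate.
// Artificial variables are represented only as basis labels (their
// columns are never stored), pivots are column-major rank-1 updates,
// and Dantzig pricing falls back to Bland's rule to guard against
// cycling on the highly degenerate flux-balance polytopes.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double EPS = 1e-9;

// One simplex phase on tableau T (m x (N+1), rhs in last column) with
// reduced-cost row obj (length N+1; last entry = -objval).  basis[i] is
// the column basic in row i; values >= N denote artificials.  Columns
// with allowed[j] == false never enter.  Returns 0 optimal, 2 unbounded,
// 3 iteration limit.
static int run_phase(mat &T, rowvec &obj, uvec &basis,
                     const std::vector<bool> &allowed, int max_iter) {
  const uword m = T.n_rows, N = T.n_cols - 1;
  int iter = 0;
  const int bland_after = 6 * (int)(m + N);
  while (true) {
    if (++iter > max_iter) return 3;
    sword enter = -1;
    if (iter <= bland_after) {  // Dantzig: most negative reduced cost
      double best = -EPS;
      for (uword j = 0; j < N; ++j)
        if (allowed[j] && obj[j] < best) { best = obj[j]; enter = j; }
    } else {                    // Bland: first negative, anti-cycling
      for (uword j = 0; j < N; ++j)
        if (allowed[j] && obj[j] < -EPS) { enter = j; break; }
    }
    if (enter < 0) return 0;
    // ratio test (ties to the smallest basis label, anti-cycling)
    sword leave = -1;
    double best_ratio = datum::inf;
    const double *col = T.colptr(enter);
    for (uword i = 0; i < m; ++i) {
      if (col[i] > EPS) {
        double r = T(i, N) / col[i];
        if (r < best_ratio - EPS ||
            (r < best_ratio + EPS && (leave < 0 || basis[i] < basis[leave])))
          { best_ratio = r; leave = i; }
      }
    }
    if (leave < 0) return 2;
    // rank-1 pivot, column-wise for cache locality
    vec fcol = T.col(enter);
    const double piv = fcol[leave];
    fcol[leave] = 0.0;
    T.row(leave) /= piv;
    rowvec prow = T.row(leave);
    for (uword j = 0; j <= N; ++j) {
      const double pj = prow[j];
      if (pj != 0.0 && j != (uword)enter) T.col(j) -= pj * fcol;
    }
    T.col(enter).zeros();
    T(leave, enter) = 1.0;
    const double fo = obj[enter];
    if (fo != 0.0) obj -= fo * prow;
    basis[leave] = enter;
  }
}

// [[Rcpp::export(name = ".simplex_core")]]
Rcpp::List simplex_core(const arma::vec &cost,
                        const arma::mat &Aeq, const arma::vec &beq,
                        const arma::mat &Aub, const arma::vec &bub,
                        int max_iter = 50000) {
  const uword n = cost.n_elem;
  const uword me = Aeq.n_rows, mu = Aub.n_rows, m = me + mu;
  const uword N = n + mu;  // structural + slack

  // rows: [Aeq 0; Aub I] | rhs, sign-flipped so rhs >= 0
  mat T(m, N + 1, fill::zeros);
  for (uword i = 0; i < me; ++i) {
    T(i, span(0, n - 1)) = Aeq.row(i);
    T(i, N) = beq[i];
  }
  for (uword i = 0; i < mu; ++i) {
    T(me + i, span(0, n - 1)) = Aub.row(i);
    T(me + i, n + i) = 1.0;
    T(me + i, N) = bub[i];
  }
  uvec basis(m);
  for (uword i = 0; i < m; ++i) {
    if (T(i, N) < 0) T.row(i) *= -1.0;
    basis[i] = N + i;  // artificial, basic at value rhs
  }

  // phase 1: minimise the sum of artificials (priced-out objective)
  rowvec obj1(N + 1, fill::zeros);
  for (uword i = 0; i < m; ++i) obj1 -= T.row(i);
  std::vector<bool> allow(N, true);
  int st = run_phase(T, obj1, basis, allow, max_iter);
  if (st == 3) return Rcpp::List::create(Rcpp::Named("status") = 3);
  if (-obj1[N] > 1e-6) return Rcpp::List::create(Rcpp::Named("status") = 1);

  // drive remaining zero-level artificials out of the basis if possible
  for (uword i = 0; i < m; ++i) {
    if (basis[i] >= N) {
      sword enter = -1;
      for (uword j = 0; j < N; ++j)
        if (std::abs(T(i, j)) > EPS) { enter = j; break; }
      if (enter >= 0) {
        vec fcol = T.col(enter);
        const double piv = fcol[i];
        fcol[i] = 0.0;
        T.row(i) /= piv;
        rowvec prow = T.row(i);
        for (uword j = 0; j <= N; ++j) {
          const double pj = prow[j];
          if (pj != 0.0 && j != (uword)enter) T.col(j) -= pj * fcol;
        }
        T.col(enter).zeros();
        T(i, enter) = 1.0;
        basis[i] = enter;
      }
      // else: redundant row; the artificial stays basic at zero
    }
  }

  // phase 2
  rowvec obj2(N + 1, fill::zeros);
  for (uword j = 0; j < n; ++j) obj2[j] = cost[j];
  for (uword i = 0; i < m; ++i) {
    const uword bj = basis[i];
    const double cb = (bj < n) ? cost[bj] : 0.0;
    if (cb != 0.0) obj2 -= cb * T.row(i);
  }
  st = run_phase(T, obj2, basis, allow, max_iter);
  if (st != 0) return Rcpp::List::create(Rcpp::Named("status") = st);

  vec x(n, fill::zeros);
  for (uword i = 0; i < m; ++i)
    if (basis[i] < n) x[basis[i]] = T(i, N);
  return Rcpp::List::create(Rcpp::Named("status") = 0,
                            Rcpp::Named("x") = x,
                            Rcpp::Named("objval") = dot(cost, x));
}
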
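#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Phase-1 feasibility test for A_ub x <= b_ub, A_eq x = b_eq,
// lower <= x <= upper, done entirely in compiled code: variable
// shifting/splitting, slack and artificial columns, and the tableau
// iterations. Returns true when a feasible point exists. This is the
// hot path of the branch-and-prune enumeration.
// [[Rcpp::export]]
bool lp_feasible_cpp(NumericMatrix A_ub, NumericVector b_ub,
                     NumericMatrix A_eq, NumericVector b_eq,
                     NumericVector lower, NumericVector upper,
                     double tol) {
  const int n = lower.size();
  const int m_ub0 = A_ub.nrow();
  const int m_eq = A_eq.nrow();

  // variable transform x = off + sign * y (or split into two columns)
  std::vector<int> col_var, col_sign;
  std::vector<double> off(n, 0.0);
  std::vector<int> first_col(n, -1);
  std::vector<double> cap; // y_k <= cap rows from two-sided bounds
  std::vector<int> cap_col;
  for (int j = 0; j < n; ++j) {
    double l = lower[j], u = upper[j];
    if (l > u + tol) return false;
    if (R_finite(l)) {
      off[j] = l;
      first_col[j] = col_var.size();
      col_var.push_back(j); col_sign.push_back(1);
      if (R_finite(u)) {
        if (u - l <= tol) { /* fixed variable: y forced ~0, keep cap */ }
        cap.push_back(u - l);
        cap_col.push_back(first_col[j]);
      }
    } else if (R_finite(u)) {
      off[j] = u;
      first_col[j] = col_var.size();
      col_var.push_back(j); col_sign.push_back(-1);
    } else {
      first_col[j] = col_var.size();
      col_var.push_back(j); col_sign.push_back(1);
      col_var.push_back(j); col_sign.push_back(-1);
    }
  }
  const int ny = col_var.size();
  const int m_ub = m_ub0 + (int)cap.size();
  const int m = m_ub + m_eq;
  if (m == 0) return true;
  const int N = ny + m_ub; // structural + slack
  // rhs after shifting
  std::vector<double> rhs(m);
  for (int r = 0; r < m_ub0; ++r) {
    double b = b_ub[r];
    for (int j = 0; j < n; ++j) b -= A_ub(r, j) * off[j];
    rhs[r] = b;
  }
  for (size_t k = 0; k < cap.size(); ++k) rhs[m_ub0 + k] = cap[k];
  for (int r = 0; r < m_eq; ++r) {
    double b = b_eq[r];
    for (int j = 0; j < n; ++j) b -= A_eq(r, j) * off[j];
    rhs[m_ub + r] = b;
  }
  // row sign flips for non-negative rhs
  std::vector<int> flip(m, 1);
  for (int r = 0; r < m; ++r) if (rhs[r] < 0) { flip[r] = -1; rhs[r] = -rhs[r]; }
  // artificials for equality rows and flipped <= rows
  std::vector<int> art_of_row(m, -1);
  int n_art = 0;
  for (int r = 0; r < m; ++r) {
    bool need = (r >= m_ub) || (flip[r] < 0);
    if (need) art_of_row[r] = n_art++;
  }
  if (n_art == 0) return true; // slack basis is feasible
  const int nc = N + n_art;
  // dense tableau
  std::vector<double> Tab((size_t)m * (nc + 1), 0.0);
  auto T = [&](int i, int j) -> double& { return Tab[(size_t)i * (nc + 1) + j]; };
  for (int r = 0; r < m; ++r) {
    const bool is_cap = (r >= m_ub0 && r < m_ub);
    for (int k = 0; k < ny; ++k) {
      double a;
      if (is_cap) {
        a = (k == cap_col[r - m_ub0]) ? 1.0 : 0.0;
      } else {
        int j = col_var[k];
        a = (r < m_ub0 ? A_ub(r, j) : A_eq(r - m_ub, j)) * col_sign[k];
      }
      if (a != 0.0) T(r, k) = flip[r] * a;
    }
    if (r < m_ub) T(r, ny + r) = flip[r] * 1.0; // slack
    if (art_of_row[r] >= 0) T(r, N + art_of_row[r]) = 1.0;
    T(r, nc) = rhs[r];
  }
  std::vector<int> basis(m);
  for (int r = 0; r < m; ++r) {
    basis[r] = (art_of_row[r] >= 0) ? N + art_of_row[r] : ny + r;
  }
  // phase 1: minimise sum of artificials (cost 1 on artificial columns)
  auto art_sum = [&]() {
    double s = 0.0;
    for (int r = 0; r < m; ++r) if (basis[r] >= N) s += T(r, nc);
    return s;
  };
  bool bland = false;
  int stall = 0;
  double last = R_PosInf;
  const int max_iter = 200 * (m + nc);
  for (int it = 0; it < max_iter; ++it) {
    if (art_sum() <= 1e-10) return true;
    // reduced costs: c_j - sum over artificial-basic rows of T(r, j)
    int pc = -1;
    double best = -tol;
    for (int j = 0; j < nc; ++j) {
      double red = (j >= N) ? 1.0 : 0.0;
      for (int r = 0; r < m; ++r) {
        if (basis[r] >= N) red -= T(r, j);
      }
      if (bland) {
        if (red < -tol) { pc = j; break; }
      } else if (red < best) { best = red; pc = j; }
    }
    if (pc < 0) break; // optimal
    int pr = -1;
    double best_ratio = R_PosInf;
    for (int r = 0; r < m; ++r) {
      double a = T(r, pc);
      if (a > tol) {
        double ratio = T(r, nc) / a;
        if (ratio < best_ratio - tol ||
            (ratio <= best_ratio + tol && (pr < 0 || basis[r] < basis[pr]))) {
          if (ratio < best_ratio) best_ratio = ratio;
          pr = r;
        }
      }
    }
    if (pr < 0) break; // unbounded phase 1 cannot happen; bail out
    double pv = T(pr, pc);
    for (int j = 0; j <= nc; ++j) T(pr, j) /= pv;
    for (int r = 0; r < m; ++r) {
      if (r == pr) continue;
      double f = T(r, pc);
      if (f != 0.0) for (int j = 0; j <= nc; ++j) T(r, j) -= f * T(pr, j);
    }
    basis[pr] = pc;
    double val = art_sum();
    if (val < last - tol) { stall = 0; last = val; }
    else if (++stall > 2 * (m + nc)) bland = true;
  }
  return art_sum() <= 1e-7;
}
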
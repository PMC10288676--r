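#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Full dense two-phase simplex: variable shifting/splitting, slack and
// artificial columns, phase 1, artificial pivot-out, phase 2 with
// artificials barred from entering, and solution extraction.
// status: 0 optimal, 1 infeasible, 2 unbounded, 3 iteration limit.
// [[Rcpp::export]]
List solve_lp_cpp(NumericVector obj, NumericMatrix A_ub, NumericVector b_ub,
                  NumericMatrix A_eq, NumericVector b_eq,
                  NumericVector lower, NumericVector upper,
                  bool maximize, double tol) {
  const int n = obj.size();
  const int m_ub0 = A_ub.nrow();
  const int m_eq = A_eq.nrow();
  NumericVector xout(n, NA_REAL);

  std::vector<int> col_var, col_sign;
  std::vector<double> off(n, 0.0);
  std::vector<double> cap;
  std::vector<int> cap_col;
  for (int j = 0; j < n; ++j) {
    double l = lower[j], u = upper[j];
    if (l > u + tol)
      return List::create(_["status"] = 1, _["x"] = xout, _["value"] = NA_REAL);
    if (R_finite(l)) {
      if (R_finite(u)) { cap.push_back(u - l); cap_col.push_back(col_var.size()); }
      off[j] = l; col_var.push_back(j); col_sign.push_back(1);
    } else if (R_finite(u)) {
      off[j] = u; col_var.push_back(j); col_sign.push_back(-1);
    } else {
      col_var.push_back(j); col_sign.push_back(1);
      col_var.push_back(j); col_sign.push_back(-1);
    }
  }
  const int ny = col_var.size();
  const int m_ub = m_ub0 + (int)cap.size();
  const int m = m_ub + m_eq;
  std::vector<double> cvec(ny);
  double sgn = maximize ? -1.0 : 1.0;
  for (int k = 0; k < ny; ++k) cvec[k] = sgn * obj[col_var[k]] * col_sign[k];
  if (m == 0) {
    for (int k = 0; k < ny; ++k) {
      if (cvec[k] < -tol)
        return List::create(_["status"] = 2, _["x"] = xout, _["value"] = NA_REAL);
    }
    double val = 0.0;
    for (int j = 0; j < n; ++j) { xout[j] = off[j]; val += obj[j] * off[j]; }
    return List::create(_["status"] = 0, _["x"] = xout, _["value"] = val);
  }

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
  std::vector<int> flip(m, 1);
  for (int r = 0; r < m; ++r) if (rhs[r] < 0) { flip[r] = -1; rhs[r] = -rhs[r]; }
  std::vector<int> art_of_row(m, -1);
  int n_art = 0;
  for (int r = 0; r < m; ++r) {
    if (r >= m_ub || flip[r] < 0) art_of_row[r] = n_art++;
  }
  const int N = ny + m_ub;
  const int nc = N + n_art;
  std::vector<double> Tab((size_t)m * (nc + 1), 0.0);
  auto T = [&](int i, int j) -> double& { return Tab[(size_t)i * (nc + 1) + j]; };
  for (int r = 0; r < m; ++r) {
    const bool is_cap = (r >= m_ub0 && r < m_ub);
    for (int k = 0; k < ny; ++k) {
      double a;
      if (is_cap) a = (k == cap_col[r - m_ub0]) ? 1.0 : 0.0;
      else {
        int j = col_var[k];
        a = (r < m_ub0 ? A_ub(r, j) : A_eq(r - m_ub, j)) * col_sign[k];
      }
      if (a != 0.0) T(r, k) = flip[r] * a;
    }
    if (r < m_ub) T(r, ny + r) = flip[r] * 1.0;
    if (art_of_row[r] >= 0) T(r, N + art_of_row[r]) = 1.0;
    T(r, nc) = rhs[r];
  }
  std::vector<int> basis(m);
  for (int r = 0; r < m; ++r)
    basis[r] = (art_of_row[r] >= 0) ? N + art_of_row[r] : ny + r;

  std::vector<double> cost(nc, 0.0);
  const int max_iter = 200 * (m + nc);

  auto pivot = [&](int pr, int pc) {
    double pv = T(pr, pc);
    for (int j = 0; j <= nc; ++j) T(pr, j) /= pv;
    for (int r = 0; r < m; ++r) {
      if (r == pr) continue;
      double f = T(r, pc);
      if (f != 0.0) for (int j = 0; j <= nc; ++j) T(r, j) -= f * T(pr, j);
    }
    basis[pr] = pc;
  };

  auto run = [&](int allowed_max, bool phase1) -> int {
    // returns 0 optimal, 2 unbounded, 3 iteration limit
    bool bland = false;
    int stall = 0;
    double last = R_PosInf;
    for (int it = 0; it < max_iter; ++it) {
      if (phase1) {
        double s = 0.0;
        for (int r = 0; r < m; ++r) if (basis[r] >= N) s += T(r, nc);
        if (s <= 1e-11) return 0;
      }
      int pc = -1;
      double best = -tol;
      for (int j = 0; j < allowed_max; ++j) {
        double red = cost[j];
        for (int r = 0; r < m; ++r) {
          double cb = cost[basis[r]];
          if (cb != 0.0) red -= cb * T(r, j);
        }
        if (bland) { if (red < -tol) { pc = j; break; } }
        else if (red < best) { best = red; pc = j; }
      }
      if (pc < 0) return 0;
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
      if (pr < 0) return 2;
      pivot(pr, pc);
      double val = 0.0;
      for (int r = 0; r < m; ++r) val += cost[basis[r]] * T(r, nc);
      if (val < last - tol) { stall = 0; last = val; }
      else if (++stall > 2 * (m + nc)) bland = true;
    }
    return 3;
  };

  if (n_art > 0) {
    for (int j = N; j < nc; ++j) cost[j] = 1.0;
    int st = run(nc, true);
    if (st == 3)
      return List::create(_["status"] = 3, _["x"] = xout, _["value"] = NA_REAL);
    double feas = 0.0;
    for (int r = 0; r < m; ++r) if (basis[r] >= N) feas += T(r, nc);
    if (feas > 1e-7)
      return List::create(_["status"] = 1, _["x"] = xout, _["value"] = NA_REAL);
    // drive remaining artificials out of the basis
    for (int r = 0; r < m; ++r) {
      if (basis[r] < N) continue;
      int pc = -1; double bestp = 1e-9;
      for (int j = 0; j < N; ++j) {
        double a = std::abs(T(r, j));
        if (a > bestp) { bestp = a; pc = j; }
      }
      if (pc >= 0) pivot(r, pc);
    }
  }
  for (int j = 0; j < nc; ++j) cost[j] = (j < ny) ? cvec[j] : 0.0;
  int st = run(N, false); // artificials barred
  if (st == 2)
    return List::create(_["status"] = 2, _["x"] = xout, _["value"] = NA_REAL);
  if (st == 3)
    return List::create(_["status"] = 3, _["x"] = xout, _["value"] = NA_REAL);
  std::vector<double> y(nc, 0.0);
  for (int r = 0; r < m; ++r) y[basis[r]] = T(r, nc);
  for (int j = 0; j < n; ++j) xout[j] = off[j];
  for (int k = 0; k < ny; ++k) xout[col_var[k]] += col_sign[k] * y[k];
  double val = 0.0;
  for (int j = 0; j < n; ++j) val += obj[j] * xout[j];
  return List::create(_["status"] = 0, _["x"] = xout, _["value"] = val);
}
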
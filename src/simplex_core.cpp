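#include <Rcpp.h>
using namespace Rcpp;

// Tableau simplex iterations. Tab is m x (nc+1) with the rhs in the
// last column; basis holds 1-based basic column indices; allowed marks
// columns permitted to enter (phase-2 bars artificials). Dantzig rule
// with a Bland fallback after prolonged stalling. status: 0 optimal,
// 1 unbounded, 2 iteration limit.
// [[Rcpp::export]]
List simplex_core_cpp(NumericMatrix Tab, IntegerVector basis,
                      NumericVector cost, LogicalVector allowed,
                      double tol, int max_iter, double stop_at) {
  int m = Tab.nrow();
  int ncol1 = Tab.ncol();
  int nc = ncol1 - 1;
  bool bland = false;
  int stall = 0;
  double last_val = R_PosInf;
  int status = 2;

  for (int it = 0; it < max_iter; ++it) {
    double val = 0.0;
    for (int i = 0; i < m; ++i) val += cost[basis[i] - 1] * Tab(i, nc);
    if (val <= stop_at) { status = 0; break; }
    // reduced costs
    int pc = -1;
    double best = -tol;
    for (int j = 0; j < nc; ++j) {
      if (!allowed[j]) continue;
      double red = cost[j];
      for (int i = 0; i < m; ++i) {
        double cb = cost[basis[i] - 1];
        if (cb != 0.0) red -= cb * Tab(i, j);
      }
      if (bland) {
        if (red < -tol) { pc = j; break; }
      } else if (red < best) {
        best = red; pc = j;
      }
    }
    if (pc < 0) { status = 0; break; }
    // ratio test
    int pr = -1;
    double best_ratio = R_PosInf;
    for (int i = 0; i < m; ++i) {
      double a = Tab(i, pc);
      if (a > tol) {
        double ratio = Tab(i, nc) / a;
        if (ratio < best_ratio - tol ||
            (ratio <= best_ratio + tol &&
             (pr < 0 || basis[i] < basis[pr]))) {
          if (ratio < best_ratio) best_ratio = ratio;
          pr = i;
        }
      }
    }
    if (pr < 0) { status = 1; break; }
    // pivot
    double pv = Tab(pr, pc);
    for (int j = 0; j < ncol1; ++j) Tab(pr, j) /= pv;
    for (int i = 0; i < m; ++i) {
      if (i == pr) continue;
      double f = Tab(i, pc);
      if (f != 0.0) {
        for (int j = 0; j < ncol1; ++j) Tab(i, j) -= f * Tab(pr, j);
      }
    }
    basis[pr] = pc + 1;
    double new_val = 0.0;
    for (int i = 0; i < m; ++i) new_val += cost[basis[i] - 1] * Tab(i, nc);
    if (new_val < last_val - tol) { stall = 0; last_val = new_val; }
    else if (++stall > 2 * (m + nc)) bland = true;
  }
  return List::create(_["Tab"] = Tab, _["basis"] = basis,
                      _["status"] = status);
}
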
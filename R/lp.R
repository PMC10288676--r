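# Dense two-phase simplex for small linear programs.
#
# All systems handled by this package are small (tens to a few hundred
# variables), so a dense tableau implementation is adequate and keeps the
# solver free of external dependencies. Free variables are split, bounded
# variables shifted, and every row normalised to a non-negative right-hand
# side before phase 1.

#' Solve a linear program
#'
#' Minimises (or maximises) `obj' x` subject to `A_ub x <= b_ub`,
#' `A_eq x = b_eq` and `lower <= x <= upper`. Intended for the small dense
#' systems arising from inner flux-optimisation problems and from the
#' linearised complementarity relaxations; not a general-purpose solver.
#'
#' @param obj objective coefficient vector.
#' @param A_ub,b_ub inequality constraints (may be `NULL`).
#' @param A_eq,b_eq equality constraints (may be `NULL`).
#' @param lower,upper variable bounds, recycled to `length(obj)`;
#'   default is free below and above.
#' @param maximize maximise instead of minimise.
#' @param tol pivot / feasibility tolerance.
#' @return list with `status` (`"optimal"`, `"infeasible"`,
#'   `"unbounded"` or `"iteration_limit"`), `x` and `value`.
#' @keywords internal
solve_lp <- function(obj, A_ub = NULL, b_ub = NULL, A_eq = NULL, b_eq = NULL,
                     lower = -Inf, upper = Inf, maximize = FALSE,
                     tol = 1e-9) {
  n <- length(obj)
  if (is.null(A_ub)) A_ub <- matrix(0, 0L, n) else A_ub <- matrix(A_ub, ncol = n)
  if (is.null(A_eq)) A_eq <- matrix(0, 0L, n) else A_eq <- matrix(A_eq, ncol = n)
  res <- solve_lp_cpp(as.numeric(obj), A_ub,
                      if (is.null(b_ub)) numeric(0) else as.numeric(b_ub),
                      A_eq,
                      if (is.null(b_eq)) numeric(0) else as.numeric(b_eq),
                      rep_len(as.numeric(lower), n),
                      rep_len(as.numeric(upper), n),
                      isTRUE(maximize), tol)
  list(status = c("optimal", "infeasible", "unbounded",
                  "iteration_limit")[res$status + 1L],
       x = res$x, value = res$value)
}

#' Check feasibility of a linear constraint system
#'
#' Phase-1 feasibility test for `A_ub x <= b_ub`, `A_eq x = b_eq`,
#' `lower <= x <= upper`.
#'
#' @inheritParams solve_lp
#' @return `TRUE` if a feasible point exists.
#' @keywords internal
lp_feasible <- function(n, A_ub = NULL, b_ub = NULL, A_eq = NULL, b_eq = NULL,
                        lower = -Inf, upper = Inf) {
  if (is.null(A_ub)) A_ub <- matrix(0, 0L, n)
  if (is.null(A_eq)) A_eq <- matrix(0, 0L, n)
  lp_feasible_cpp(A_ub, if (is.null(b_ub)) numeric(0) else b_ub,
                  A_eq, if (is.null(b_eq)) numeric(0) else b_eq,
                  rep_len(lower, n), rep_len(upper, n), 1e-9)
}
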
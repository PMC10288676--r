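# Branch-and-bound for mixed binary linear programs.
#
# The only integrality this package ever needs is the binary activation
# vector of the linearised complementary-slackness conditions, so the
# solver handles {0,1} variables only. Bounding uses the LP relaxation,
# branching picks the most fractional binary, and exploration is
# depth-first (good incumbents arrive early because slack minima are
# usually attained with few active constraints).

#' Solve a small mixed binary linear program
#'
#' Minimises `obj' x` subject to linear constraints and `x[binary] in {0,1}`.
#'
#' @inheritParams solve_lp
#' @param binary integer indices of binary variables.
#' @param time_limit wall-clock budget in seconds; on expiry the best
#'   incumbent is returned with status `"time_limit"`.
#' @param int_tol integrality tolerance on the relaxation.
#' @param target stop as soon as an incumbent reaches this objective
#'   value (useful when the objective has a known lower bound).
#' @return list with `status` (`"optimal"`, `"time_limit"`,
#'   `"infeasible"`), `x`, `value` and `nodes` (nodes explored).
#' @keywords internal
solve_milp <- function(obj, A_ub = NULL, b_ub = NULL, A_eq = NULL, b_eq = NULL,
                       lower = -Inf, upper = Inf, binary = integer(0),
                       time_limit = 60, int_tol = 1e-6, target = -Inf) {
  n <- length(obj)
  lower <- rep_len(lower, n)
  upper <- rep_len(upper, n)
  lower[binary] <- pmax(lower[binary], 0)
  upper[binary] <- pmin(upper[binary], 1)
  t0 <- proc.time()[["elapsed"]]

  best <- list(x = NULL, value = Inf)
  nodes <- 0L
  hit_limit <- FALSE
  stack <- list(list(lo = lower, up = upper))

  while (length(stack)) {
    if (proc.time()[["elapsed"]] - t0 > time_limit) { hit_limit <- TRUE; break }
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    nodes <- nodes + 1L
    rel <- solve_lp(obj, A_ub, b_ub, A_eq, b_eq, node$lo, node$up)
    if (rel$status != "optimal") next
    if (rel$value >= best$value - 1e-9) next
    frac <- abs(rel$x[binary] - round(rel$x[binary]))
    if (!length(binary) || max(frac) <= int_tol) {
      x <- rel$x
      x[binary] <- round(x[binary])
      best <- list(x = x, value = rel$value)
      if (best$value <= target) break # provably good enough
      next
    }
    j <- binary[which.max(frac)]
    lo1 <- node$lo; up1 <- node$up
    lo0 <- node$lo; up0 <- node$up
    up0[j] <- 0; lo1[j] <- 1
    # explore the branch closer to the relaxation value last (DFS pops tail)
    if (rel$x[j] >= 0.5) {
      stack[[length(stack) + 1L]] <- list(lo = lo0, up = up0)
      stack[[length(stack) + 1L]] <- list(lo = lo1, up = up1)
    } else {
      stack[[length(stack) + 1L]] <- list(lo = lo1, up = up1)
      stack[[length(stack) + 1L]] <- list(lo = lo0, up = up0)
    }
  }

  if (is.null(best$x)) {
    status <- if (hit_limit) "time_limit" else "infeasible"
    return(list(status = status, x = rep(NA_real_, n), value = NA_real_,
                nodes = nodes))
  }
  list(status = if (hit_limit) "time_limit" else "optimal",
       x = best$x, value = best$value, nodes = nodes)
}
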
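# First numerical stage: fix the abundance vector to a grid, linearise
# complementary slackness with big-M binaries, add paired non-negative
# slacks to the abundance-coupled equalities, and minimise total slack
# with a small mixed binary program per grid point.

#' Big-M constant for the linearised complementarity conditions
#'
#' Conservative bound on the multiplier and slack magnitudes appearing
#' in the linearised system: ten times the largest of the inflow
#' concentrations, the constant bound pieces, the dilution-scaled inflow
#' and one.
#'
#' @param model a [community_model()].
#' @param env a chemostat [environment_spec()].
#' @return positive scalar.
#' @export
choose_omega <- function(model, env) {
  if (!env$mode %in% c("CA", "CC"))
    stop("choose_omega applies to the chemostat modes")
  consts <- unlist(lapply(model$species, function(sp)
    lapply(sp$b, function(b) vapply(b$pieces, function(p)
      abs(p$intercept), 0))))
  10 * max(max(env$C_in, 0), if (length(consts)) max(consts) else 0,
           env$D * max(env$C_in, 0), 1)
}

#' Linearised complementary slackness constraints
#'
#' For every inequality-multiplier pair `(lambda_1j, q_j)` emits the
#' four big-M rows `0 <= lambda_1j <= Omega Delta_j` and
#' `-Omega (1 - Delta_j) <= q_j <= 0` over the variable block
#' `[nu, C, lambda1, Delta]`, with `Delta` binary. Capacity rows use
#' the bound piece selected in `piece_choice` (relevant only for
#' piecewise bounds).
#'
#' @param system a chemostat [assemble_system()] result.
#' @param omega big-M constant, see [choose_omega()].
#' @param piece_choice integer vector (one entry per capacity row)
#'   selecting the active bound piece; `NULL` = first piece.
#' @return list with `A_ub`, `b_ub` over columns
#'   `[nu (n_nu), C (n_C), lambda1 (n_l1), Delta (n_l1)]`, plus the
#'   column offsets.
#' @export
linearize_complementarity <- function(system, omega, piece_choice = NULL) {
  if (!system$mode %in% c("CA", "CC"))
    stop("linearised complementarity applies to the chemostat systems")
  nnu_tot <- sum(system$nnu)
  n_C <- system$n_C
  n_l1 <- length(system$layout$l1)
  nv <- nnu_tot + n_C + 2L * n_l1
  o_C <- nnu_tot; o_l <- nnu_tot + n_C; o_d <- o_l + n_l1
  rows <- list(); rhs <- numeric(0)
  add <- function(r, v) { rows[[length(rows) + 1L]] <<- r; rhs <<- c(rhs, v) }
  for (j in seq_len(n_l1)) {
    kind <- system$pair_kind[j]; ref <- system$pair_ref[j]
    # q_j as a linear expression qv . [nu, C] - q0
    qv <- numeric(nnu_tot + n_C); q0 <- 0
    if (kind == "cap") {
      pc <- if (is.null(piece_choice)) 1L else piece_choice[ref]
      p <- system$bounds[[ref]]$pieces[[pc]]
      qv[seq_len(nnu_tot)] <- system$Ablk[ref, ]
      qv[nnu_tot + seq_len(n_C)] <- -p$gradient
      q0 <- p$intercept
    } else { # Cnn
      qv[nnu_tot + ref] <- -1
    }
    # lambda_j <= Omega Delta_j
    r <- numeric(nv); r[o_l + j] <- 1; r[o_d + j] <- -omega; add(r, 0)
    # -lambda_j <= 0
    r <- numeric(nv); r[o_l + j] <- -1; add(r, 0)
    # q_j <= 0
    r <- numeric(nv); r[seq_len(nnu_tot + n_C)] <- qv; add(r, q0)
    # -q_j <= Omega (1 - Delta_j)
    r <- numeric(nv); r[seq_len(nnu_tot + n_C)] <- -qv; r[o_d + j] <- omega
    add(r, omega - q0)
  }
  list(A_ub = do.call(rbind, rows), b_ub = rhs,
       offsets = list(nu = 0L, C = o_C, lambda1 = o_l, delta = o_d),
       n_pairs = n_l1)
}

#' Abundance grid specification
#'
#' @param lower,upper per-species abundance bounds (finite,
#'   `lower <= upper`).
#' @param points points per axis (>= 1), linear spacing.
#' @return object of class `grid_spec`.
#' @export
grid_spec <- function(lower, upper, points) {
  stopifnot(length(lower) == length(upper), all(is.finite(lower)),
            all(is.finite(upper)), all(lower <= upper), points >= 1)
  structure(list(lower = lower, upper = upper, points = as.integer(points)),
            class = "grid_spec")
}

# enumerate active-piece combinations for multi-piece bounds (each with
# linear validity cuts chosen piece <= other pieces), keeping every MILP
# purely linear
piece_combinations <- function(system, max_combos = 256L) {
  np <- vapply(system$bounds, function(b) length(b$pieces), 1L)
  if (prod(np) > max_combos)
    stop("too many bound piece combinations for the grid stage")
  grid <- do.call(expand.grid, lapply(np, seq_len))
  lapply(seq_len(nrow(grid)), function(r) as.integer(grid[r, ]))
}

#' Minimal-slack solve at one fixed abundance vector
#'
#' With the abundances fixed, the equality rows that contain the
#' abundance vector (chemostat mass balance and D-growth) may be
#' infeasible, so each receives a pair of non-negative slack variables;
#' the mixed binary program minimises their L1 sum subject to all other
#' constraints and the linearised complementarity conditions. A zero
#' optimum certifies a steady state on the grid point.
#'
#' @param system a chemostat [assemble_system()] result.
#' @param omega big-M constant.
#' @param fixed_abundances non-negative abundance vector (length
#'   `n_X`).
#' @param time_limit per-point solver budget, seconds.
#' @return object of class `grid_result`: `point`, `slack` (L1
#'   optimum), `max_violation`, `candidate` (a
#'   [steady_state_solution()]; `NULL` when infeasible), `status`
#'   (`"optimal"`, `"time_limit"`, `"infeasible"`).
#' @export
solve_at_point <- function(system, omega, fixed_abundances, time_limit = 60) {
  if (!system$mode %in% c("CA", "CC"))
    stop("the grid stage applies to the chemostat systems")
  stopifnot(length(fixed_abundances) == system$n_X,
            all(fixed_abundances >= 0))
  X <- fixed_abundances
  env <- system$env
  nnu_tot <- sum(system$nnu)
  n_C <- system$n_C; n_X <- system$n_X
  n_l1 <- length(system$layout$l1)
  n_l2 <- length(system$layout$l2)
  n_sl <- n_C + n_X
  # variables: nu | C | l1 | l2 | s+ | s- | Delta
  o_C <- nnu_tot; o_l1 <- o_C + n_C; o_l2 <- o_l1 + n_l1
  o_sp <- o_l2 + n_l2; o_sm <- o_sp + n_sl; o_d <- o_sm + n_sl
  nv <- o_d + n_l1
  lower <- rep(-Inf, nv); upper <- rep(Inf, nv)
  lower[o_C + seq_len(n_C)] <- 0
  lower[o_l1 + seq_len(n_l1)] <- 0; upper[o_l1 + seq_len(n_l1)] <- omega
  lower[o_sp + seq_len(2L * n_sl)] <- 0
  lower[o_d + seq_len(n_l1)] <- 0; upper[o_d + seq_len(n_l1)] <- 1
  obj <- numeric(nv); obj[o_sp + seq_len(2L * n_sl)] <- 1

  best <- NULL
  sum_growth <- identical(system$objective, "sum_growth")
  w <- if (sum_growth) as.numeric(X > support_threshold) else X
  for (pc in piece_combinations(system)) {
    Ae <- list(); be <- numeric(0)
    add_eq <- function(r, v) { Ae[[length(Ae) + 1L]] <<- r; be <<- c(be, v) }
    # mass balance with slacks: D C + sum_i X_i T_i nu_i - s+ + s- = D C_in
    for (c_ in seq_len(n_C)) {
      r <- numeric(nv); r[o_C + c_] <- env$D
      for (i in seq_len(n_X)) {
        r[system$layout$nu[[i]]] <- X[i] * system$model$species[[i]]$T[c_, ]
      }
      r[o_sp + c_] <- -1; r[o_sm + c_] <- 1
      add_eq(r, env$D * env$C_in[c_])
    }
    # D-growth rows: -X_i nu_g + s+ - s- = -X_i D
    for (i in seq_len(n_X)) {
      r <- numeric(nv); r[system$g_idx[i]] <- -X[i]
      r[o_sp + n_C + i] <- 1; r[o_sm + n_C + i] <- -1
      add_eq(r, -X[i] * env$D)
    }
    for (rr in seq_len(nrow(system$Sblk))) {
      r <- numeric(nv); r[seq_len(nnu_tot)] <- system$Sblk[rr, ]; add_eq(r, 0)
    }
    # KKT stationarity at fixed X
    for (i in seq_len(n_X)) {
      sp <- system$model$species[[i]]
      for (k in seq_len(ncol(sp$S))) {
        r <- numeric(nv)
        r[o_l1 + system$l1A_of_sp[[i]]] <- sp$A[, k]
        r[o_l2 + system$l2S_of_sp[[i]]] <- sp$S[, k]
        v <- 0
        if (system$mode == "CA") {
          v <- as.numeric(k == sp$growth_index)
        } else {
          v <- w[i] * as.numeric(k == sp$growth_index)
          r[o_l2 + length(system$layout$l2S) + seq_len(n_C)] <- -X[i] * sp$T[, k]
        }
        add_eq(r, v)
      }
    }
    if (system$mode == "CC") {
      G <- t(vapply(seq_along(system$bounds), function(j)
        system$bounds[[j]]$pieces[[pc[j]]]$gradient, numeric(n_C)))
      for (c_ in seq_len(n_C)) {
        r <- numeric(nv)
        r[o_l1 + seq_along(system$layout$l1A)] <- -G[, c_]
        r[o_l1 + length(system$layout$l1A) + c_] <- -1
        r[o_l2 + length(system$layout$l2S) + c_] <- -env$D
        add_eq(r, 0)
      }
    }
    # inequalities: all capacity pieces + piece validity + big-M rows
    Au <- list(); bu <- numeric(0)
    add_ub <- function(r, v) { Au[[length(Au) + 1L]] <<- r; bu <<- c(bu, v) }
    for (j in seq_along(system$bounds)) {
      pieces <- system$bounds[[j]]$pieces
      for (p in pieces) {
        r <- numeric(nv); r[seq_len(nnu_tot)] <- system$Ablk[j, ]
        r[o_C + seq_len(n_C)] <- -p$gradient
        add_ub(r, p$intercept)
      }
      if (length(pieces) > 1L) {
        star <- pieces[[pc[j]]]
        for (k in seq_along(pieces)) {
          if (k == pc[j]) next
          p <- pieces[[k]]
          r <- numeric(nv)
          r[o_C + seq_len(n_C)] <- star$gradient - p$gradient
          add_ub(r, p$intercept - star$intercept)
        }
      }
    }
    lin <- linearize_complementarity(system, omega, piece_choice = pc)
    map <- c(seq_len(nnu_tot + n_C), o_l1 + seq_len(n_l1),
             o_d + seq_len(n_l1))
    Alin <- matrix(0, nrow(lin$A_ub), nv)
    Alin[, map] <- lin$A_ub
    milp <- solve_milp(obj,
                       A_ub = rbind(do.call(rbind, Au), Alin),
                       b_ub = c(bu, lin$b_ub),
                       A_eq = do.call(rbind, Ae), b_eq = be,
                       lower = lower, upper = upper,
                       binary = o_d + seq_len(n_l1),
                       time_limit = time_limit,
                       target = 1e-10) # the slack sum cannot go below 0
    if (milp$status == "infeasible") next
    if (is.null(best) || (is.finite(milp$value) && milp$value < best$value)) {
      best <- c(milp, list(pc = pc))
    }
    if (!is.null(best) && is.finite(best$value) && best$value < 1e-9) break
  }
  if (is.null(best)) {
    return(structure(list(point = X, slack = NA_real_,
                          max_violation = NA_real_, candidate = NULL,
                          status = "infeasible"),
                     class = "grid_result"))
  }
  v <- best$x
  z <- numeric(system$n_z)
  z[seq_len(nnu_tot)] <- v[seq_len(nnu_tot)]
  z[system$layout$C] <- v[o_C + seq_len(n_C)]
  z[system$layout$X] <- X
  z[system$layout$l1] <- v[o_l1 + seq_len(n_l1)]
  z[system$layout$l2] <- v[o_l2 + seq_len(n_l2)]
  cand <- z_to_solution(system, z, branch = complementarity_pattern(
    round(v[o_d + seq_len(n_l1)]), as.integer(X > support_threshold)))
  # Omega saturation: re-solve once with a ten-fold constant
  lam <- v[o_l1 + seq_len(n_l1)]
  if (any(lam > 0.99 * omega)) {
    return(solve_at_point(system, 10 * omega, X, time_limit))
  }
  structure(list(point = X, slack = best$value,
                 max_violation = cand$residual_max, candidate = cand,
                 status = best$status),
            class = "grid_result")
}

#' @export
print.grid_result <- function(x, ...) {
  cat(sprintf("grid_result at X=(%s): slack %.3g, status %s\n",
              paste(signif(x$point, 4), collapse = ", "),
              x$slack, x$status))
  invisible(x)
}

#' Map the minimal slack over an abundance grid
#'
#' Runs [solve_at_point()] on every point of a linearly spaced abundance
#' grid (row-major order: the first species varies slowest). Points that
#' hit the time limit are retained and flagged.
#'
#' @param system a chemostat [assemble_system()] result.
#' @param omega big-M constant.
#' @param grid a [grid_spec()].
#' @param time_limit per-point budget, seconds.
#' @return list of `grid_result`, one per point.
#' @export
map_grid <- function(system, omega, grid, time_limit = 60) {
  n_X <- system$n_X
  stopifnot(length(grid$lower) == n_X)
  axes <- lapply(seq_len(n_X), function(i)
    seq(grid$lower[i], grid$upper[i], length.out = grid$points))
  pts <- as.matrix(do.call(expand.grid, rev(axes)))[, n_X:1, drop = FALSE]
  lapply(seq_len(nrow(pts)), function(r)
    solve_at_point(system, omega, as.numeric(pts[r, ]), time_limit))
}
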
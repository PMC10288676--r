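# Exact enumeration solver for small models.
#
# Every steady state of the assembled system lies on some complementarity
# branch: each inequality/multiplier pair is either active (constraint
# tight, multiplier free and non-negative) or inactive (multiplier zero),
# and each species is either absent or growing at the dilution rate
# (batch: at the community rate). Enumerating the branches and solving
# each resulting square polynomial system recovers the complete solution
# set, which is what a symbolic solver would return.
#
# The full branch space is 2^(|lambda1| + n_X). `enumerate_solutions`
# traverses it depth-first and prunes a subtree as soon as a *linear
# relaxation* of the branch-prefix constraints is LP-infeasible. The
# relaxation drops only bilinear rows (or divides them by an abundance
# known to be positive, which preserves feasibility), so pruning is
# sound: no feasible branch is ever skipped. The relaxation separates
# into a primal part (fluxes, concentrations, abundand fractions) and a
# dual part (multipliers) with no shared variables, and each assignment
# touches exactly one part, so only that part is re-checked.

#' Complementarity/support pattern
#'
#' @param delta 0/1 vector, one entry per inequality-multiplier pair
#'   (1 = constraint active, multiplier free; 0 = multiplier zero).
#' @param support 0/1 vector over species (1 = species present, growing
#'   at the dilution rate or at the community rate).
#' @return object of class `complementarity_pattern`.
#' @export
complementarity_pattern <- function(delta, support) {
  structure(list(delta = as.integer(delta), support = as.integer(support)),
            class = "complementarity_pattern")
}

#' Enumerate all complementarity/support patterns
#'
#' @param system an [assemble_system()] result.
#' @param max_patterns enumeration budget; the total pattern count
#'   `2^(|lambda1| + n_X)` must not exceed it, otherwise an error signals
#'   that the model is too large for the oracle and the grid stage
#'   should be used instead.
#' @return object of class `pattern_iterator` with fields `count`,
#'   `n_delta`, `n_support` and a function `get(i)` returning the i-th
#'   pattern (1-based).
#' @export
enumerate_patterns <- function(system, max_patterns = 2^22) {
  n_delta <- length(system$layout$l1)
  n_support <- system$n_X
  nbits <- n_delta + n_support
  count <- 2^nbits
  if (count > max_patterns) {
    stop(sprintf(
      "pattern budget exceeded: 2^%d = %g patterns > max_patterns = %g; %s",
      nbits, count, max_patterns,
      "model too large for the enumeration oracle, use the grid stage"))
  }
  get <- function(i) {
    stopifnot(i >= 1, i <= count)
    bits <- as.integer(intToBits(i - 1L))[seq_len(nbits)]
    complementarity_pattern(delta = bits[n_support + seq_len(n_delta)],
                            support = bits[seq_len(n_support)])
  }
  structure(list(count = count, n_delta = n_delta, n_support = n_support,
                 get = get),
            class = "pattern_iterator")
}

# ---- pattern-restricted square system ----------------------------------

# Residual and analytic Jacobian of the pattern-restricted system as
# functions of the reduced unknown vector. The system is at most
# quadratic, so the Jacobian splits into a precomputed constant part and
# a small set of bilinear updates; the indicator weights of the
# sum-of-growth objective and the active bound pieces are piecewise
# constant. With `include_species` a subset of species can be dropped
# entirely (used for zero-abundance species, whose decoupled
# single-species KKT subsystem is attached after the fact).
pattern_system <- function(system, pattern, include_species = NULL) {
  lay <- system$layout
  chemostat <- system$mode %in% c("CA", "CC")
  mode <- system$mode
  supp <- pattern$support > 0
  delta <- pattern$delta > 0
  env <- system$env
  n_X <- system$n_X; n_C <- system$n_C
  spl <- system$model$species
  sum_growth <- identical(system$objective, "sum_growth")
  z_base <- numeric(system$n_z)
  incl <- if (is.null(include_species)) rep(TRUE, n_X) else include_species
  incl_idx <- which(incl)
  # pairs belonging to excluded species are neither imposed nor solved
  pair_incl <- rep(TRUE, length(delta))
  pair_incl[system$pair_kind == "cap"] <-
    incl[system$sp_of_Arow[system$pair_ref[system$pair_kind == "cap"]]]
  delta <- delta & pair_incl
  unknown <- c(unlist(lay$nu[incl]),
               if (chemostat) c(lay$C, lay$X[supp & incl]),
               if (!chemostat) c(lay$x[supp & incl], lay$mu_star),
               lay$l1[delta], unlist(lapply(incl_idx, function(i)
                 lay$l2S[system$l2S_of_sp[[i]]])), lay$l2C)
  n_v <- length(unknown)
  col_of <- integer(system$n_z)
  col_of[unknown] <- seq_len(n_v)
  act <- which(delta)
  act_kind <- system$pair_kind[act]
  act_ref <- system$pair_ref[act]
  Tm <- lapply(spl, `[[`, "T")
  Am <- lapply(spl, `[[`, "A")
  Sm <- lapply(spl, `[[`, "S")
  gl <- vapply(spl, `[[`, 1L, "growth_index")
  multi_piece <- vapply(system$bounds, function(b) length(b$pieces) > 1L, TRUE)

  # ---- row layout -----------------------------------------------------
  n_core <- if (chemostat) n_C + sum(supp) else sum(supp) + 1L
  r_mass <- if (chemostat) seq_len(n_C)
  r_grow <- if (chemostat) n_C + seq_len(sum(supp)) else seq_len(sum(supp))
  r_sumx <- if (!chemostat) sum(supp) + 1L
  r_S <- n_core + seq_len(nrow(system$Sblk))
  r_stat <- list(); ro <- n_core + nrow(system$Sblk)
  for (i in incl_idx) { r_stat[[as.character(i)]] <- ro + seq_len(system$nnu[i]); ro <- ro + system$nnu[i] }
  r_statC <- if (mode == "CC") ro + seq_len(n_C)
  if (mode == "CC") ro <- ro + n_C
  r_act <- if (length(act)) ro + seq_along(act)
  n_eq <- ro + length(act)

  fn <- function(v) {
    z <- z_base
    z[unknown] <- v
    nu <- z[lay$nu_all]
    out <- numeric(n_eq)
    if (chemostat) {
      C <- z[lay$C]; X <- z[lay$X]
      acc <- numeric(n_C)
      for (i in incl_idx) {
        acc <- acc + as.vector(Tm[[i]] %*% z[lay$nu[[i]]]) * X[i]
      }
      out[r_mass] <- env$D * (env$C_in - C) - acc
      out[r_grow] <- env$D - nu[system$g_idx[supp]]
      # the sum-of-growth objective weight is the declared support of
      # the branch (constant on the branch), keeping the system polynomial
      w <- if (sum_growth) as.numeric(supp) else X
    } else {
      x <- z[lay$x]
      out[r_grow] <- z[lay$mu_star] - nu[system$g_idx[supp]]
      out[r_sumx] <- sum(x) - 1
      w <- if (sum_growth) as.numeric(supp) else x
    }
    out[r_S] <- as.vector(system$Sblk %*% nu)
    for (i in incl_idx) {
      s <- as.vector(crossprod(Am[[i]], z[lay$l1A][system$l1A_of_sp[[i]]]) +
                     crossprod(Sm[[i]], z[lay$l2S][system$l2S_of_sp[[i]]]))
      if (mode %in% c("CA", "BA")) {
        s[gl[i]] <- s[gl[i]] - 1
      } else if (mode == "CC") {
        s[gl[i]] <- s[gl[i]] - w[i]
        s <- s - z[lay$X][i] * as.vector(crossprod(Tm[[i]], z[lay$l2C]))
      } else { # BC
        s[gl[i]] <- s[gl[i]] - w[i]
        s <- s + z[lay$x][i] * as.vector(crossprod(Tm[[i]], z[lay$l1u]))
      }
      out[r_stat[[as.character(i)]]] <- s
    }
    if (mode == "CC") {
      C <- z[lay$C]
      G <- bound_gradient(system$bounds, C)
      out[r_statC] <- as.vector(-crossprod(G, z[lay$l1A])) - z[lay$l1C] -
        env$D * z[lay$l2C]
    }
    if (length(act)) {
      qv <- numeric(length(act))
      for (k in seq_along(act)) {
        ref <- act_ref[k]
        qv[k] <- switch(act_kind[k],
          cap = sum(system$Ablk[ref, ] * nu) -
            evaluate_bounds(system$bounds[ref],
                            if (chemostat) z[lay$C] else rep(0, n_C)),
          Cnn = -z[lay$C][ref],
          culture = {
            a <- 0
            for (i in incl_idx) {
              a <- a + sum(Tm[[i]][ref, ] * z[lay$nu[[i]]]) * z[lay$x][i]
            }
            a - env$u[ref]
          })
      }
      out[r_act] <- qv
    }
    out
  }

  # ---- constant Jacobian part ----------------------------------------
  put <- function(J, rows, zcols, val) {
    cc <- col_of[zcols]
    keep <- cc > 0L
    if (any(keep)) J[rows, cc[keep]] <- (if (is.matrix(val))
      val[, keep, drop = FALSE] else val[keep])
    J
  }
  J0 <- matrix(0, n_eq, n_v)
  if (chemostat) {
    J0 <- put(J0, r_mass, lay$C, diag(-env$D, n_C))
    k <- 0L
    for (i in which(supp)) {
      k <- k + 1L
      J0[r_grow[k], col_of[lay$nu[[i]][gl[i]]]] <- -1
    }
  } else {
    k <- 0L
    for (i in which(supp)) {
      k <- k + 1L
      J0[r_grow[k], col_of[lay$mu_star]] <- 1
      J0[r_grow[k], col_of[lay$nu[[i]][gl[i]]]] <- -1
    }
    J0 <- put(J0, r_sumx, lay$x, rep(1, n_X))
  }
  J0 <- put(J0, r_S, lay$nu_all, system$Sblk)
  for (i in incl_idx) {
    rows <- r_stat[[as.character(i)]]
    J0 <- put(J0, rows, lay$l1A[system$l1A_of_sp[[i]]], t(Am[[i]]))
    J0 <- put(J0, rows, lay$l2S[system$l2S_of_sp[[i]]], t(Sm[[i]]))
  }
  statC_const <- mode == "CC" && !any(multi_piece)
  if (mode == "CC") {
    J0 <- put(J0, r_statC, lay$l1C, diag(-1, n_C))
    J0 <- put(J0, r_statC, lay$l2C, diag(-env$D, n_C))
    if (statC_const) {
      G <- t(vapply(system$bounds, function(b) b$pieces[[1L]]$gradient,
                    numeric(n_C)))
      J0 <- put(J0, r_statC, lay$l1A, -t(G))
    }
  }
  for (k in seq_along(act)) {
    ref <- act_ref[k]
    if (act_kind[k] == "cap") {
      J0 <- put(J0, r_act[k], lay$nu_all, system$Ablk[ref, ])
      if (chemostat && !multi_piece[ref]) {
        J0 <- put(J0, r_act[k], lay$C,
                  -system$bounds[[ref]]$pieces[[1L]]$gradient)
      }
    } else if (act_kind[k] == "Cnn") {
      J0[r_act[k], col_of[lay$C[ref]]] <- -1
    }
  }

  jac <- function(v) {
    z <- z_base
    z[unknown] <- v
    J <- J0
    if (chemostat) {
      X <- z[lay$X]
      for (i in incl_idx) {
        J <- put(J, r_mass, lay$nu[[i]], -X[i] * Tm[[i]])
        ci <- col_of[lay$X[i]]
        if (ci > 0L) J[r_mass, ci] <- -as.vector(Tm[[i]] %*% z[lay$nu[[i]]])
      }
    }
    for (i in incl_idx) {
      rows <- r_stat[[as.character(i)]]
      if (mode == "CC") {
        J <- put(J, rows, lay$l2C, -z[lay$X][i] * t(Tm[[i]]))
        ci <- col_of[lay$X[i]]
        if (ci > 0L) {
          dd <- -as.vector(crossprod(Tm[[i]], z[lay$l2C]))
          if (!sum_growth) dd[gl[i]] <- dd[gl[i]] - 1
          J[rows, ci] <- dd
        }
      } else if (mode == "BC") {
        J <- put(J, rows, lay$l1u, z[lay$x][i] * t(Tm[[i]]))
        ci <- col_of[lay$x[i]]
        if (ci > 0L) {
          dd <- as.vector(crossprod(Tm[[i]], z[lay$l1u]))
          if (!sum_growth) dd[gl[i]] <- dd[gl[i]] - 1
          J[rows, ci] <- dd
        }
      }
    }
    if (mode == "CC" && !statC_const) {
      G <- bound_gradient(system$bounds, z[lay$C])
      J <- put(J, r_statC, lay$l1A, -t(G))
    }
    for (k in seq_along(act)) {
      ref <- act_ref[k]
      if (act_kind[k] == "cap" && chemostat && multi_piece[ref]) {
        J <- put(J, r_act[k], lay$C,
                 -bound_gradient(system$bounds[ref], z[lay$C])[1L, ])
      } else if (act_kind[k] == "culture") {
        for (i in incl_idx) {
          J <- put(J, r_act[k], lay$nu[[i]], Tm[[i]][ref, ] * z[lay$x][i])
          ci <- col_of[lay$x[i]]
          if (ci > 0L) J[r_act[k], ci] <- sum(Tm[[i]][ref, ] * z[lay$nu[[i]]])
        }
      }
    }
    J
  }

  # fast evaluator: the system is exactly quadratic in the unknowns when
  # every bound is a single affine piece, so F(v) = F0 + J0 v + Q(v)
  # with Q holding only the abundance-flux and abundance-multiplier
  # products
  fn_out <- fn
  if (!any(multi_piece)) {
    v0 <- numeric(n_v)
    F0 <- fn(v0)
    J0q <- jac(v0)
    c_nu <- lapply(seq_len(n_X), function(i) col_of[lay$nu[[i]]])
    c_X <- if (chemostat) col_of[lay$X]
    c_x <- if (!chemostat) col_of[lay$x]
    c_l2C <- if (mode == "CC") col_of[lay$l2C]
    c_l1u <- if (mode == "BC") col_of[lay$l1u]
    getv <- function(v, cc) ifelse(cc > 0L, v[pmax(cc, 1L)], 0)
    fn_out <- function(v) {
      out <- F0 + as.vector(J0q %*% v)
      if (chemostat) {
        X <- getv(v, c_X)
        for (i in incl_idx) {
          if (X[i] == 0) next
          tn <- as.vector(Tm[[i]] %*% getv(v, c_nu[[i]]))
          out[r_mass] <- out[r_mass] - X[i] * tn
          if (mode == "CC") {
            out[r_stat[[as.character(i)]]] <-
              out[r_stat[[as.character(i)]]] -
              X[i] * as.vector(crossprod(Tm[[i]], getv(v, c_l2C)))
          }
        }
      } else {
        x <- getv(v, c_x)
        for (i in incl_idx) {
          if (x[i] == 0) next
          if (mode == "BC") {
            out[r_stat[[as.character(i)]]] <-
              out[r_stat[[as.character(i)]]] +
              x[i] * as.vector(crossprod(Tm[[i]], getv(v, c_l1u)))
          }
        }
        for (k in seq_along(act)) {
          if (act_kind[k] != "culture") next
          ref <- act_ref[k]
          a <- 0
          for (i in incl_idx) {
            a <- a + sum(Tm[[i]][ref, ] * getv(v, c_nu[[i]])) * x[i]
          }
          out[r_act[k]] <- out[r_act[k]] + a
        }
      }
      out
    }
  }
  list(fn = fn_out, jac = jac, unknown = unknown, z_base = z_base, n_v = n_v)
}
# damped root finding on a (possibly rank-deficient) square polynomial
# system via Levenberg-Marquardt; returns the root or NULL
newton_root <- function(fn, v0, jac = NULL, maxit = 35, tol = 1e-11) {
  f0 <- fn(v0)
  if (any(!is.finite(f0))) return(NULL)
  fit <- tryCatch(
    suppressWarnings(minpack.lm::nls.lm(
      par = v0, fn = fn, jac = jac,
      control = minpack.lm::nls.lm.control(
        maxiter = maxit, ftol = 1e-15, ptol = 1e-15,
        maxfev = 20000))),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  v <- fit$par
  if (max(abs(fn(v))) < tol) v else NULL
}

#' Solve one complementarity pattern
#'
#' Fixes a pattern (active constraints imposed as equalities, inactive
#' multipliers zeroed, species supports fixed), solves the resulting
#' square polynomial system by damped Gauss-Newton from one
#' deterministic and `n_starts` seeded random starts, and keeps roots
#' whose full-system residual is below `1e-8` with all inequalities
#' satisfied.
#'
#' @param system an [assemble_system()] result.
#' @param pattern a [complementarity_pattern()].
#' @param n_starts number of random starts.
#' @param seed RNG seed for the random starts.
#' @return list of [steady_state_solution()] objects (empty if the
#'   branch is infeasible), deduplicated at `1e-8`.
#' @export
solve_pattern <- function(system, pattern, n_starts = 20, seed = 1) {
  ps <- pattern_system(system, pattern)
  lay <- system$layout
  chemostat <- system$mode %in% c("CA", "CC")
  env <- system$env
  scale_C <- if (chemostat) max(env$C_in, 1) else max(abs(env$u), 1)

  det_start <- function() {
    z <- ps$z_base
    if (chemostat) {
      z[lay$C] <- env$C_in
      z[lay$X] <- ifelse(pattern$support > 0, 1, 0)
    } else {
      ns <- max(1L, sum(pattern$support))
      z[lay$x] <- ifelse(pattern$support > 0, 1 / ns, 0)
      z[lay$mu_star] <- 1
    }
    z[lay$l1] <- ifelse(pattern$delta > 0, 0.5, 0)
    z
  }
  rand_start <- function() {
    z <- ps$z_base
    z[lay$nu_all] <- stats::runif(length(lay$nu_all), -scale_C, scale_C)
    if (chemostat) {
      z[lay$C] <- stats::runif(system$n_C, 0, scale_C)
      z[lay$X] <- ifelse(pattern$support > 0,
                         stats::runif(system$n_X, 0, 3), 0)
    } else {
      xs <- stats::runif(system$n_X)
      xs[pattern$support == 0] <- 0
      if (sum(xs) > 0) xs <- xs / sum(xs)
      z[lay$x] <- xs
      z[lay$mu_star] <- stats::runif(1, 0, 3)
    }
    z[lay$l1] <- ifelse(pattern$delta > 0, stats::runif(length(lay$l1), 0, 2), 0)
    z[lay$l2] <- stats::runif(length(lay$l2), -1, 1)
    z
  }

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  roots <- list(); root_z <- list()
  starts <- c(list(det_start()), replicate(n_starts, rand_start(), simplify = FALSE))
  for (z0 in starts) {
    v <- newton_root(ps$fn, z0[ps$unknown], jac = ps$jac)
    if (is.null(v)) next
    z <- ps$z_base; z[ps$unknown] <- v
    dup <- any(vapply(root_z, function(r) max(abs(r - z)) < 1e-8, TRUE))
    if (dup) next
    sol <- z_to_solution(system, z, branch = pattern)
    if (!is.finite(sol$residual_max) || sol$residual_max > 1e-8) next
    roots[[length(roots) + 1L]] <- sol
    root_z[[length(root_z) + 1L]] <- z
  }
  roots
}


# ---- pruned depth-first enumeration ------------------------------------

# slack margin for inactive inequalities during enumeration: a pair
# assigned inactive must show at least this slack, so that every steady
# state is enumerated exactly under the pattern matching its active set
# (a constraint tight with a zero multiplier is found on its active
# branch, where the multiplier is merely required to be non-negative).
# Steady states in which an inactive constraint has slack below the
# margin would be missed; the margin is far below any constraint scale
# used in practice.
strict_margin <- 1e-7

# precomputed structures for the primal/dual relaxation parts.
# The primal part works on (nu, C | x, mu_star) plus lifted
# abundance-weighted fluxes phi_i = X_i nu_i (x_i nu_i in batch), which
# make the chemostat mass balance, the culture bound and the homogeneous
# capacity cone linear.
relax_base <- function(system) {
  env <- system$env
  mode <- system$mode
  chemostat <- mode %in% c("CA", "CC")
  sum_growth <- identical(system$objective, "sum_growth")
  n_X <- system$n_X; n_C <- system$n_C
  nnu_tot <- sum(system$nnu)
  n_l1A <- length(system$layout$l1A)
  nS_tot <- sum(system$nS)

  # ---- primal part ----------------------------------------------------
  # vars: nu | C (chemostat) or x, mu_star (batch) | phi
  n_mid <- if (chemostat) n_C else n_X + 1L
  nvP <- nnu_tot + n_mid + nnu_tot
  i_nu <- seq_len(nnu_tot)
  i_C <- if (chemostat) nnu_tot + seq_len(n_C)
  i_x <- if (!chemostat) nnu_tot + seq_len(n_X)
  i_ms <- if (!chemostat) nnu_tot + n_X + 1L
  i_phi <- nnu_tot + n_mid + seq_len(nnu_tot)
  phi_of_sp <- lapply(seq_len(n_X), function(i)
    i_phi[system$nu_off[i] + seq_len(system$nnu[i])])
  lowerP <- rep(-Inf, nvP)
  if (chemostat) lowerP[i_C] <- 0 else lowerP[i_x] <- 0

  AeqP <- list(); beqP <- numeric(0)
  AubP <- list(); bubP <- numeric(0)
  add_eq <- function(r, v) { AeqP[[length(AeqP) + 1L]] <<- r; beqP <<- c(beqP, v) }
  add_ub <- function(r, v) { AubP[[length(AubP) + 1L]] <<- r; bubP <<- c(bubP, v) }
  zero <- function() numeric(nvP)
  # intracellular balance for nu and phi
  for (r in seq_len(nrow(system$Sblk))) {
    rr <- zero(); rr[i_nu] <- system$Sblk[r, ]; add_eq(rr, 0)
    rr <- zero(); rr[i_phi] <- system$Sblk[r, ]; add_eq(rr, 0)
  }
  if (chemostat) {
    # mass balance: D C + sum_i T phi = D C_in
    for (c_ in seq_len(n_C)) {
      rr <- zero(); rr[i_C[c_]] <- env$D; rr[i_phi] <- system$Tcat[c_, ]
      add_eq(rr, env$D * env$C_in[c_])
    }
  } else {
    rr <- zero(); rr[i_x] <- 1; add_eq(rr, 1)
    # culture bound on lifted fluxes: sum_i T phi_i <= u
    for (c_ in seq_len(n_C)) {
      rr <- zero(); rr[i_phi] <- system$Tcat[c_, ]
      add_ub(rr, env$u[c_])
    }
  }
  # capacity pieces on nu; homogeneous constant-zero rows also on phi
  for (j in seq_len(n_l1A)) {
    pieces <- system$bounds[[j]]$pieces
    for (p in pieces) {
      rr <- zero(); rr[i_nu] <- system$Ablk[j, ]
      if (chemostat) rr[i_C] <- -p$gradient
      add_ub(rr, p$intercept)
    }
    if (length(pieces) == 1L && pieces[[1L]]$intercept == 0 &&
        all(pieces[[1L]]$gradient == 0)) {
      rr <- zero(); rr[i_phi] <- system$Ablk[j, ]; add_ub(rr, 0)
    }
  }
  AeqP <- do.call(rbind, AeqP); AubP <- do.call(rbind, AubP)

  # per-pair rows (built on demand): active equality / strict-slack rows
  pair_rows <- function(j, active) {
    kind <- system$pair_kind[j]; ref <- system$pair_ref[j]
    if (kind == "cap") {
      pieces <- system$bounds[[ref]]$pieces
      if (active) {
        if (length(pieces) > 1L) return(NULL) # not linearisable
        p <- pieces[[1L]]
        rr <- zero(); rr[i_nu] <- system$Ablk[ref, ]
        if (chemostat) rr[i_C] <- -p$gradient
        return(list(eq = rr, eq_rhs = p$intercept))
      }
      rows <- lapply(pieces, function(p) {
        rr <- zero(); rr[i_nu] <- system$Ablk[ref, ]
        if (chemostat) rr[i_C] <- -p$gradient
        rr
      })
      return(list(ub = do.call(rbind, rows),
                  ub_rhs = vapply(pieces, function(p) p$intercept, 0) -
                    strict_margin))
    }
    if (kind == "culture") {
      rr <- zero(); rr[i_phi] <- system$model$species[[1L]]$T[ref, ] * 0
      rr[i_phi] <- system$Tcat[ref, ]
      if (active) return(list(eq = rr, eq_rhs = env$u[ref]))
      return(list(ub = rbind(rr), ub_rhs = env$u[ref] - strict_margin))
    }
    NULL # Cnn handled through variable bounds
  }
  # support rows: growth pinned for supported, phi zeroed for absent
  sup_row <- matrix(0, n_X, nvP); sup_rhs <- numeric(n_X)
  for (i in seq_len(n_X)) {
    sup_row[i, system$g_idx[i]] <- 1
    if (chemostat) sup_rhs[i] <- env$D else sup_row[i, i_ms] <- -1
  }

  # ---- dual part (supported species only) -----------------------------
  nvD <- n_l1A + nS_tot + (if (mode == "CC") n_C else 0L) +
    (if (mode == "BC") n_C else 0L) + (if (sum_growth) n_X else 0L)
  j_lt <- seq_len(n_l1A)
  j_l2 <- n_l1A + seq_len(nS_tot)
  j_w <- if (mode == "CC") n_l1A + nS_tot + seq_len(n_C)
  j_lu <- if (mode == "BC") n_l1A + nS_tot + seq_len(n_C)
  j_t <- if (sum_growth) nvD - n_X + seq_len(n_X)
  lowerD <- rep(-Inf, nvD)
  lowerD[j_lt] <- 0
  if (mode == "BC") lowerD[j_lu] <- 0
  if (sum_growth) lowerD[j_t] <- 0
  dual_block <- function(i) {
    sp <- system$model$species[[i]]
    nr <- ncol(sp$S)
    M <- matrix(0, nr, nvD); v <- numeric(nr)
    M[, j_lt[system$l1A_of_sp[[i]]]] <- t(sp$A)
    M[, j_l2[system$l2S_of_sp[[i]]]] <- t(sp$S)
    if (mode %in% c("CA", "BA")) {
      v[sp$growth_index] <- 1
    } else {
      if (mode == "CC") M[, j_w] <- -t(sp$T)
      if (mode == "BC") M[, j_lu] <- t(sp$T)
      if (sum_growth) M[sp$growth_index, j_t[i]] <- -1
      else v[sp$growth_index] <- 1
    }
    list(A = M, b = v)
  }

  # lite variant (no lifted-flux block) drops the phi columns and every
  # row touching them; used for the cheap mid-tree checks
  nvL <- nnu_tot + n_mid

  # prestacked per-pair rows, so that a node check is a row subset
  n_pairs <- length(system$layout$l1)
  eq_rows <- list(); eq_rhs2 <- numeric(0); eq_pair_of <- integer(0)
  ub_rows <- list(); ub_rhs2 <- numeric(0); ub_pair_of <- integer(0)
  for (j in seq_len(n_pairs)) {
    pr <- pair_rows(j, active = TRUE)
    if (!is.null(pr) && !is.null(pr$eq)) {
      eq_rows[[length(eq_rows) + 1L]] <- pr$eq
      eq_rhs2 <- c(eq_rhs2, pr$eq_rhs); eq_pair_of <- c(eq_pair_of, j)
    }
    pr <- pair_rows(j, active = FALSE)
    if (!is.null(pr) && !is.null(pr$ub)) {
      for (r in seq_len(nrow(pr$ub))) {
        ub_rows[[length(ub_rows) + 1L]] <- pr$ub[r, ]
        ub_rhs2 <- c(ub_rhs2, pr$ub_rhs[r]); ub_pair_of <- c(ub_pair_of, j)
      }
    }
  }
  Peq <- rbind(AeqP, sup_row, do.call(rbind, eq_rows))
  peq_rhs <- c(beqP, sup_rhs, eq_rhs2)
  n_base_eq <- nrow(AeqP)
  Pub <- rbind(AubP, do.call(rbind, ub_rows))
  pub_rhs <- c(bubP, ub_rhs2)
  n_base_ub <- nrow(AubP)
  has_phi_eq <- apply(Peq[, i_phi, drop = FALSE] != 0, 1L, any)
  has_phi_ub <- apply(Pub[, i_phi, drop = FALSE] != 0, 1L, any)

  list(chemostat = chemostat, mode = mode,
       nvP = nvP, nvL = nvL, i_C = i_C, i_x = i_x, phi_of_sp = phi_of_sp,
       lowerP = lowerP,
       Peq = Peq, peq_rhs = peq_rhs, n_base_eq = n_base_eq,
       Pub = Pub, pub_rhs = pub_rhs, n_base_ub = n_base_ub,
       eq_pair_of = eq_pair_of, ub_pair_of = ub_pair_of,
       has_phi_eq = has_phi_eq, has_phi_ub = has_phi_ub,
       n_X = n_X,
       pair_rows = pair_rows, sup_row = sup_row, sup_rhs = sup_rhs,
       nvD = nvD, j_lt = j_lt, j_lu = j_lu, lowerD = lowerD,
       dual_block = dual_block)
}

relax_primal_ok <- function(rb, system, supp, delta, lite = FALSE) {
  active <- !is.na(delta) & delta == 1L
  inactive <- !is.na(delta) & delta == 0L
  sel_eq <- c(seq_len(rb$n_base_eq), rb$n_base_eq + which(supp == 1L),
              rb$n_base_eq + rb$n_X + which(active[rb$eq_pair_of]))
  sel_ub <- c(seq_len(rb$n_base_ub),
              rb$n_base_ub + which(inactive[rb$ub_pair_of]))
  if (lite) {
    sel_eq <- sel_eq[!rb$has_phi_eq[sel_eq]]
    sel_ub <- sel_ub[!rb$has_phi_ub[sel_ub]]
  }
  nv <- if (lite) rb$nvL else rb$nvP
  cols <- seq_len(nv)
  lower <- rb$lowerP[cols]
  upper <- rep(Inf, nv)
  if (!lite) {
    for (i in which(supp != 1L)) {
      lower[rb$phi_of_sp[[i]]] <- 0; upper[rb$phi_of_sp[[i]]] <- 0
    }
  }
  if (!rb$chemostat) upper[rb$i_x[which(supp != 1L)]] <- 0
  for (j in which(!is.na(delta) & system$pair_kind == "Cnn")) {
    ref <- system$pair_ref[j]
    if (delta[j] == 1L) upper[rb$i_C[ref]] <- 0
    else lower[rb$i_C[ref]] <- strict_margin
  }
  lp_feasible(nv,
              A_ub = rb$Pub[sel_ub, cols, drop = FALSE],
              b_ub = rb$pub_rhs[sel_ub],
              A_eq = rb$Peq[sel_eq, cols, drop = FALSE],
              b_eq = rb$peq_rhs[sel_eq],
              lower = lower, upper = upper)
}

relax_dual_ok <- function(rb, system, supp, delta, prebuilt = NULL) {
  keep <- which(supp == 1L)
  if (!length(keep)) return(TRUE)
  if (is.null(prebuilt)) {
    blocks <- lapply(keep, rb$dual_block)
    Ae <- do.call(rbind, lapply(blocks, `[[`, "A"))
    be <- unlist(lapply(blocks, `[[`, "b"))
  } else {
    Ae <- prebuilt$A; be <- prebuilt$b
  }
  upper <- rep(Inf, rb$nvD)
  for (j in seq_along(delta)) {
    if (is.na(delta[j]) || delta[j] == 1L) next
    kind <- system$pair_kind[j]; ref <- system$pair_ref[j]
    if (kind == "cap") upper[rb$j_lt[ref]] <- 0
    if (kind == "culture") upper[rb$j_lu[ref]] <- 0
  }
  lp_feasible(rb$nvD, A_eq = Ae, b_eq = be, lower = rb$lowerD, upper = upper)
}

# attach the decoupled KKT subsystem of zero-abundance species to a
# solved core vector z; returns the completed z or NULL when a species'
# inner problem admits no KKT point (unbounded growth)
attach_unsupported <- function(system, z, supp) {
  lay <- system$layout
  chemostat <- system$mode %in% c("CA", "CC")
  Cfix <- if (chemostat) z[lay$C] else rep(0, system$n_C)
  for (i in which(supp == 0L)) {
    sp <- system$model$species[[i]]
    bC <- evaluate_bounds(sp$b, Cfix)
    n_nu <- ncol(sp$S)
    if (system$mode %in% c("CA", "BA")) {
      obj <- numeric(n_nu); obj[sp$growth_index] <- 1
      pr <- solve_lp(obj, A_ub = sp$A, b_ub = bC, A_eq = sp$S,
                     b_eq = rep(0, nrow(sp$S)), maximize = TRUE)
      if (pr$status != "optimal") return(NULL)
      # multipliers from the dual program
      nl <- nrow(sp$A); ns <- nrow(sp$S)
      dobj <- c(bC, rep(0, ns))
      Aeq <- cbind(t(sp$A), t(sp$S))
      beq <- obj
      du <- solve_lp(dobj, A_eq = Aeq, b_eq = beq,
                     lower = c(rep(0, nl), rep(-Inf, ns)))
      if (du$status != "optimal") return(NULL)
      z[lay$nu[[i]]] <- pr$x
      z[lay$l1A[system$l1A_of_sp[[i]]]] <- du$x[seq_len(nl)]
      z[lay$l2S[system$l2S_of_sp[[i]]]] <- du$x[nl + seq_len(ns)]
    } else {
      # community modes: zero weight and zero abundance make the
      # stationarity rows homogeneous; zero multipliers and any feasible
      # flux vector satisfy them
      if (all(bC >= -1e-12)) {
        z[lay$nu[[i]]] <- 0
      } else {
        fs <- solve_lp(rep(0, n_nu), A_ub = sp$A, b_ub = bC, A_eq = sp$S,
                       b_eq = rep(0, nrow(sp$S)))
        if (fs$status != "optimal") return(NULL)
        z[lay$nu[[i]]] <- fs$x
      }
      z[lay$l1A[system$l1A_of_sp[[i]]]] <- 0
      z[lay$l2S[system$l2S_of_sp[[i]]]] <- 0
    }
  }
  z
}

#' Enumerate all steady-state solutions of a small model
#'
#' Depth-first traversal of the complementarity/support pattern space
#' with sound linear-relaxation pruning. Zero-abundance species decouple
#' from the community system, so only the supported species' capacity
#' pairs (plus the concentration-sign and culture-bound pairs) are
#' enumerated; the absent species' single-species KKT subsystems are
#' solved separately and attached. Every surviving pattern is solved
#' with a multistart damped Newton iteration, and the union is filtered
#' by the acceptance checks (full residual below `threshold`,
#' independent inner-LP optimality gap below `1e-6`) and deduplicated.
#'
#' Solution continua (bands) are reported as isolated representatives,
#' one per converged start.
#'
#' @param model a [community_model()].
#' @param env an [environment_spec()].
#' @param max_patterns pattern budget, see [enumerate_patterns()].
#' @param n_starts random starts per surviving pattern.
#' @param seed RNG seed.
#' @param threshold acceptance threshold on the maximal constraint
#'   violation.
#' @param dedupe_tol solution deduplication tolerance in abundance /
#'   concentration space.
#' @return list of accepted [steady_state_solution()] objects, sorted by
#'   abundance vector (lexicographic).
#' @export
enumerate_solutions <- function(model, env, max_patterns = 2^22,
                                n_starts = 6, seed = 1,
                                threshold = 1e-8, dedupe_tol = 1e-6) {
  system <- assemble_system(model, env)
  enumerate_patterns(system, max_patterns) # budget check
  n_l1 <- length(system$layout$l1)
  n_X <- system$n_X
  rb <- relax_base(system)
  sols <- list()
  pat_i <- 0L

  lay <- system$layout
  chemostat <- system$mode %in% c("CA", "CC")
  mode <- system$mode
  sum_growth <- identical(system$objective, "sum_growth")
  cap_idx <- which(system$pair_kind == "cap")

  finish_root <- function(z, supp, delta) {
    # attach absent species, check the canonical labelling (enumerated
    # inactive pairs must show strict slack), full-residual check
    zfull <- attach_unsupported(system, z, supp)
    if (is.null(zfull)) return(invisible())
    Cnow <- if (chemostat) zfull[lay$C] else rep(0, system$n_C)
    qA <- as.vector(system$Ablk %*% zfull[lay$nu_all]) -
      evaluate_bounds(system$bounds, Cnow)
    for (j in which(!is.na(delta) & delta == 0L)) {
      slack <- switch(system$pair_kind[j],
        cap = -qA[system$pair_ref[j]],
        Cnn = Cnow[system$pair_ref[j]],
        culture = {
          acc <- system$env$u[system$pair_ref[j]]
          for (i in seq_len(n_X)) {
            sp <- system$model$species[[i]]
            acc <- acc - sum(sp$T[system$pair_ref[j], ] *
                               zfull[lay$nu[[i]]]) * zfull[lay$x[i]]
          }
          acc
        })
      if (slack < 1e-9) return(invisible()) # belongs to the active branch
    }
    db <- delta; db[is.na(db)] <- 0L
    db[cap_idx] <- as.integer(abs(qA[system$pair_ref[cap_idx]]) < 1e-9)
    sol <- z_to_solution(system, zfull,
                         branch = complementarity_pattern(db, supp))
    if (!is.finite(sol$residual_max) || sol$residual_max > threshold)
      return(invisible())
    sols[[length(sols) + 1L]] <<- sol
    invisible()
  }

  # min-norm least-squares solution and null-space basis
  solve_ls_affine <- function(M, b) {
    sv <- svd(M, nu = nrow(M), nv = ncol(M))
    tol <- max(dim(M)) * max(sv$d, 0) * 1e-10
    r <- sum(sv$d > tol)
    dinv <- c(1 / sv$d[seq_len(r)], rep(0, ncol(M) - r))
    ut_b <- crossprod(sv$u, b)[seq_len(ncol(M))]
    ut_b[seq_len(ncol(M)) > r] <- 0
    p <- as.vector(sv$v %*% (dinv * ut_b))
    list(p = p, resid = max(abs(M %*% p - b)),
         N = if (r < ncol(M)) sv$v[, (r + 1L):ncol(M), drop = FALSE])
  }

  # Joint linear primal solve over (nu, C, phi) with phi_i = X_i nu_i:
  # the chemostat mass balance is linear in phi, and consistency
  # phi_i = X_i nu_i (X_i = phi_growth/D) is checked afterwards.
  # Returns NULL when rank-deficient (caller falls through), TRUE when
  # handled with no root, or list(z=) with the completed primal point.
  stage0_joint <- function(supp, delta, incl, act) {
    n_incl_nu <- sum(system$nnu[incl])
    nu_cols <- unlist(lay$nu[incl])
    n_C <- system$n_C
    nun <- integer(system$n_z); nun[nu_cols] <- seq_len(n_incl_nu)
    o_C <- n_incl_nu
    o_phi <- n_incl_nu + n_C
    nuq <- 2L * n_incl_nu + n_C
    rows <- list(); rhs <- numeric(0)
    add <- function(r, v) { rows[[length(rows) + 1L]] <<- r; rhs <<- c(rhs, v) }
    k_i <- 0L
    phi_pos <- integer(system$n_z)
    for (i in which(incl)) {
      phi_pos[lay$nu[[i]]] <- o_phi + k_i + seq_len(system$nnu[i])
      k_i <- k_i + system$nnu[i]
    }
    for (i in which(incl)) {
      sp <- system$model$species[[i]]
      for (r in seq_len(nrow(sp$S))) {
        rr <- numeric(nuq); rr[nun[lay$nu[[i]]]] <- sp$S[r, ]; add(rr, 0)
        rr <- numeric(nuq); rr[phi_pos[lay$nu[[i]]]] <- sp$S[r, ]; add(rr, 0)
      }
      rr <- numeric(nuq); rr[nun[lay$nu[[i]][sp$growth_index]]] <- 1
      add(rr, system$env$D)
    }
    for (c_ in seq_len(n_C)) {
      rr <- numeric(nuq); rr[o_C + c_] <- system$env$D
      for (i in which(incl)) {
        rr[phi_pos[lay$nu[[i]]]] <- system$model$species[[i]]$T[c_, ]
      }
      add(rr, system$env$D * system$env$C_in[c_])
    }
    for (k in act) {
      kind <- system$pair_kind[k]; ref <- system$pair_ref[k]
      if (kind == "cap") {
        if (!incl[system$sp_of_Arow[ref]]) next
        p <- system$bounds[[ref]]$pieces[[1L]]
        rr <- numeric(nuq)
        rr[nun[nu_cols]] <- system$Ablk[ref, nu_cols]
        rr[o_C + seq_len(n_C)] <- -p$gradient
        add(rr, p$intercept)
        if (p$intercept == 0 && all(p$gradient == 0)) {
          rr <- numeric(nuq)
          rr[phi_pos[nu_cols]] <- system$Ablk[ref, nu_cols]
          add(rr, 0)
        }
      } else if (kind == "Cnn") {
        rr <- numeric(nuq); rr[o_C + ref] <- 1; add(rr, 0)
      }
    }
    M <- do.call(rbind, rows)
    if (is.null(M) || nrow(M) < nuq) return(NULL)
    qd <- qr(M)
    if (qd$rank < nuq) return(NULL)
    u <- qr.coef(qd, rhs)
    if (any(is.na(u))) return(NULL)
    if (max(abs(M %*% u - rhs)) > 1e-9) return(TRUE)
    z <- numeric(system$n_z)
    z[nu_cols] <- u[seq_len(n_incl_nu)]
    z[lay$C] <- u[o_C + seq_len(n_C)]
    if (any(z[lay$C] < -1e-9)) return(TRUE)
    ok <- TRUE
    for (i in which(incl)) {
      phi_i <- u[phi_pos[lay$nu[[i]]]]
      X_i <- phi_i[system$model$species[[i]]$growth_index] / system$env$D
      if (X_i < support_threshold) { ok <- FALSE; break }
      if (max(abs(phi_i - X_i * z[lay$nu[[i]]])) > 1e-9) { ok <- FALSE; break }
      z[lay$X[i]] <- X_i
    }
    if (!ok) return(TRUE)
    list(z = z)
  }

  # Fast path: when the active constraints pin the fluxes and
  # concentrations, the leaf reduces to a cascade of linear solves
  # (fluxes/concentrations -> abundances -> multipliers). Underdetermined
  # abundances (solution continua) are reported as the minimum-norm point
  # plus seeded null-space samples. Returns TRUE when handled, FALSE when
  # the leaf needs the multistart solver.
  fast_leaf <- function(supp, delta) {
    incl <- supp == 1L
    act <- which(!is.na(delta) & delta == 1L)
    if (any(vapply(system$bounds[system$pair_ref[act[system$pair_kind[act] == "cap"]]],
                   function(b) length(b$pieces) > 1L, TRUE))) return(FALSE)
    if (chemostat) {
      st0 <- stage0_joint(supp, delta, incl, act)
      if (!is.null(st0)) {
        if (is.list(st0)) lam_finish(st0$z, supp, delta, incl)
        return(TRUE)
      }
    }
    n_incl_nu <- sum(system$nnu[incl])
    nu_cols <- unlist(lay$nu[incl])
    # stage 1: (nu_incl, C) or (nu_incl, mu_star)
    n_mid <- if (chemostat) system$n_C else 1L
    n_u1 <- n_incl_nu + n_mid
    rows <- list(); rhs <- numeric(0)
    nu_pos <- integer(system$n_z); nu_pos[nu_cols] <- seq_len(n_incl_nu)
    for (i in which(incl)) {
      sp <- system$model$species[[i]]
      for (r in seq_len(nrow(sp$S))) {
        rr <- numeric(n_u1); rr[nu_pos[lay$nu[[i]]]] <- sp$S[r, ]
        rows[[length(rows) + 1L]] <- rr; rhs <- c(rhs, 0)
      }
      rr <- numeric(n_u1); rr[nu_pos[lay$nu[[i]][sp$growth_index]]] <- 1
      if (chemostat) { rows[[length(rows) + 1L]] <- rr; rhs <- c(rhs, system$env$D) }
      else { rr[n_u1] <- -1; rows[[length(rows) + 1L]] <- rr; rhs <- c(rhs, 0) }
    }
    for (k in act) {
      kind <- system$pair_kind[k]; ref <- system$pair_ref[k]
      if (kind == "cap") {
        if (!incl[system$sp_of_Arow[ref]]) next
        p <- system$bounds[[ref]]$pieces[[1L]]
        rr <- numeric(n_u1)
        rr[nu_pos[nu_cols]] <- system$Ablk[ref, nu_cols]
        if (chemostat) rr[n_incl_nu + seq_len(system$n_C)] <- -p$gradient
        rows[[length(rows) + 1L]] <- rr; rhs <- c(rhs, p$intercept)
      } else if (kind == "Cnn") {
        rr <- numeric(n_u1); rr[n_incl_nu + ref] <- 1
        rows[[length(rows) + 1L]] <- rr; rhs <- c(rhs, 0)
      }
      # culture rows are bilinear in (nu, x): handled in stage 2 at fixed nu
    }
    M1 <- do.call(rbind, rows)
    if (is.null(M1)) return(FALSE)
    q1 <- qr(M1)
    if (q1$rank < n_u1) return(FALSE) # primal continuum: multistart
    u1 <- qr.coef(q1, rhs)
    if (any(is.na(u1)) || max(abs(M1 %*% u1 - rhs)) > 1e-9)
      return(TRUE) # inconsistent: no root on this branch
    z <- numeric(system$n_z)
    z[nu_cols] <- u1[seq_len(n_incl_nu)]
    if (chemostat) z[lay$C] <- u1[n_incl_nu + seq_len(system$n_C)]
    else z[lay$mu_star] <- u1[n_u1]
    if (chemostat && any(z[lay$C] < -1e-9)) return(TRUE)

    # stage 2: abundances
    n_supp <- sum(incl)
    if (chemostat) {
      M2 <- vapply(which(incl), function(i)
        as.vector(system$model$species[[i]]$T %*% z[lay$nu[[i]]]),
        numeric(system$n_C))
      M2 <- matrix(M2, nrow = system$n_C)
      rhs2 <- system$env$D * (system$env$C_in - z[lay$C])
    } else {
      rows <- list(rep(1, n_supp)); rhs2 <- 1
      for (k in act[system$pair_kind[act] == "culture"]) {
        ref <- system$pair_ref[k]
        rows[[length(rows) + 1L]] <- vapply(which(incl), function(i)
          sum(system$model$species[[i]]$T[ref, ] * z[lay$nu[[i]]]), 0)
        rhs2 <- c(rhs2, system$env$u[ref])
      }
      M2 <- do.call(rbind, rows)
    }
    ls2 <- solve_ls_affine(M2, rhs2)
    if (ls2$resid > 1e-9) return(TRUE)
    ab_cands <- list(ls2$p)
    if (!is.null(ls2$N)) {
      for (k in seq_len(2L + 2L * ncol(ls2$N))) {
        ab_cands[[length(ab_cands) + 1L]] <-
          ls2$p + as.vector(ls2$N %*% stats::rnorm(ncol(ls2$N),
                                                   sd = max(abs(ls2$p), 1)))
      }
    }
    handled <- FALSE
    for (ab_s in ab_cands) {
      if (any(ab_s < support_threshold)) next
      zc <- z
      if (chemostat) zc[lay$X[incl]] <- ab_s else zc[lay$x[incl]] <- ab_s
      lam_finish(zc, supp, delta, incl)
      handled <- TRUE
    }
    return(TRUE)

  }

  # multipliers are linear at a fixed primal point; solve and finish
  lam_finish <- function(z, supp, delta, incl) {
    act <- which(!is.na(delta) & delta == 1L)
    lam_unknown <- c(lay$l1[!is.na(delta) & delta == 1L],
                     unlist(lapply(which(incl), function(i)
                       lay$l2S[system$l2S_of_sp[[i]]])), lay$l2C)
    if (!length(lam_unknown)) {
      finish_root(z, supp, delta)
      return(invisible())
    }
    n_u3 <- length(lam_unknown)
    lpos <- integer(system$n_z); lpos[lam_unknown] <- seq_len(n_u3)
    rows <- list(); rhs3 <- numeric(0)
    ab <- if (chemostat) z[lay$X] else z[lay$x]
    w <- if (sum_growth) as.numeric(ab > support_threshold) else ab
    for (i in which(incl)) {
      sp <- system$model$species[[i]]
      l1c <- lay$l1A[system$l1A_of_sp[[i]]]
      l2c <- lay$l2S[system$l2S_of_sp[[i]]]
      for (r in seq_len(ncol(sp$S))) {
        rr <- numeric(n_u3); v <- 0
        cc <- lpos[l1c]; sel <- cc > 0L
        rr[cc[sel]] <- sp$A[sel, r]
        rr[lpos[l2c]] <- sp$S[, r]
        if (mode %in% c("CA", "BA")) {
          v <- as.numeric(r == sp$growth_index)
        } else if (mode == "CC") {
          rr[lpos[lay$l2C]] <- -ab[i] * sp$T[, r]
          v <- w[i] * as.numeric(r == sp$growth_index)
        } else {
          cc <- lpos[lay$l1u]; sel <- cc > 0L
          rr[cc[sel]] <- ab[i] * sp$T[sel, r]
          v <- w[i] * as.numeric(r == sp$growth_index)
        }
        rows[[length(rows) + 1L]] <- rr; rhs3 <- c(rhs3, v)
      }
    }
    if (mode == "CC") {
      G <- bound_gradient(system$bounds, z[lay$C])
      for (c_ in seq_len(system$n_C)) {
        rr <- numeric(n_u3)
        cc <- lpos[lay$l1A]; sel <- cc > 0L
        rr[cc[sel]] <- -G[sel, c_]
        cc <- lpos[lay$l1C[c_]]; if (cc > 0L) rr[cc] <- -1
        rr[lpos[lay$l2C[c_]]] <- -system$env$D
        rows[[length(rows) + 1L]] <- rr; rhs3 <- c(rhs3, 0)
      }
    }
    M3 <- do.call(rbind, rows)
    q3 <- qr(M3)
    l1_mask <- lam_unknown %in% lay$l1
    if (q3$rank < n_u3) {
      # multipliers underdetermined: pick a sign-feasible one by LP
      lp <- solve_lp(rep(0, n_u3), A_eq = M3, b_eq = rhs3,
                     lower = ifelse(l1_mask, 0, -Inf))
      if (lp$status != "optimal") return(invisible())
      lam <- lp$x
    } else {
      lam <- qr.coef(q3, rhs3)
      if (any(is.na(lam)) || max(abs(M3 %*% lam - rhs3)) > 1e-9)
        return(invisible())
      if (any(lam[l1_mask] < -1e-9)) return(invisible())
      lam[l1_mask] <- pmax(lam[l1_mask], 0)
    }
    z[lam_unknown] <- lam
    finish_root(z, supp, delta)
    invisible()
  }

  solve_leaf <- function(supp, delta) {
    pat_i <<- pat_i + 1L
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed + pat_i)
    if (fast_leaf(supp, delta)) return(invisible())
    delta_full <- delta
    delta_full[is.na(delta_full)] <- 0L
    pat <- complementarity_pattern(delta_full, supp)
    incl <- supp == 1L
    ps <- pattern_system(system, pat, include_species = incl)
    scale_C <- if (chemostat) max(env$C_in, 1) else max(abs(env$u), 1)
    starts <- list()
    z0 <- ps$z_base
    if (chemostat) {
      z0[lay$C] <- env$C_in
      z0[lay$X] <- ifelse(incl, 1, 0)
    } else {
      ns <- max(1L, sum(incl))
      z0[lay$x] <- ifelse(incl, 1 / ns, 0)
      z0[lay$mu_star] <- 1
    }
    z0[lay$l1] <- ifelse(pat$delta > 0, 0.5, 0)
    starts[[1L]] <- z0
    for (k in seq_len(n_starts)) {
      zr <- ps$z_base
      zr[unlist(lay$nu[incl])] <- stats::runif(sum(system$nnu[incl]),
                                               -scale_C, scale_C)
      if (chemostat) {
        zr[lay$C] <- stats::runif(system$n_C, 0, scale_C)
        zr[lay$X[incl]] <- stats::runif(sum(incl), 0, 3)
      } else {
        xs <- stats::runif(n_X); xs[!incl] <- 0
        if (sum(xs) > 0) xs <- xs / sum(xs)
        zr[lay$x] <- xs
        zr[lay$mu_star] <- stats::runif(1, 0, 3)
      }
      zr[lay$l1] <- ifelse(pat$delta > 0, stats::runif(n_l1, 0, 2), 0)
      zr[lay$l2] <- stats::runif(length(lay$l2), -1, 1)
      starts[[k + 1L]] <- zr
    }
    seen <- list()
    fails <- 0L; isolated <- FALSE; extra <- 0L
    for (zs in starts) {
      if (isolated) {
        # the first root was locally unique (full-rank Jacobian); a
        # couple of extra starts guard against further isolated roots
        extra <- extra + 1L
        if (extra > 2L) break
      }
      v <- newton_root(ps$fn, zs[ps$unknown], jac = ps$jac)
      if (is.null(v)) {
        fails <- fails + 1L
        if (!length(seen) && fails >= 3L) break
        next
      }
      z <- ps$z_base; z[ps$unknown] <- v
      if (any(vapply(seen, function(r) max(abs(r - z)) < 1e-8, TRUE))) next
      if (!length(seen)) isolated <- qr(ps$jac(v))$rank == ps$n_v
      seen[[length(seen) + 1L]] <- z
      if (!isolated) {
        # canonical representative on a root manifold: repeatedly
        # minimise the abundance norm along the tangent space and
        # re-converge (exact for affine bands after a few sweeps)
        ab_idx <- which(ps$unknown %in% c(lay$X, lay$x))
        vpol <- v
        for (sweep in 1:4) {
          sv <- svd(ps$jac(vpol))
          tolr <- max(dim(sv$u)) * max(sv$d) * 1e-9
          null_idx <- c(which(sv$d <= tolr),
                        seq_len(ncol(sv$v))[-seq_along(sv$d)])
          if (!length(null_idx) || !length(ab_idx)) break
          N <- sv$v[, null_idx, drop = FALSE]
          A <- N[ab_idx, , drop = FALSE]
          tt <- tryCatch(qr.coef(qr(A), -vpol[ab_idx]),
                         error = function(e) NULL)
          if (is.null(tt)) break
          tt[is.na(tt)] <- 0
          step <- as.vector(N %*% tt)
          v2 <- newton_root(ps$fn, vpol + step, jac = ps$jac)
          if (is.null(v2)) break
          vpol <- v2
          if (max(abs(step)) < 1e-10) break
        }
        if (max(abs(vpol - v)) > 1e-10) {
          z2 <- ps$z_base; z2[ps$unknown] <- vpol
          if (!any(vapply(seen, function(r) max(abs(r - z2)) < 1e-8, TRUE))) {
            seen[[length(seen) + 1L]] <- z2
            finish_root(z2, supp, delta)
          }
        }
      }
      finish_root(z, supp, delta)
    }
    invisible()
  }

  dual_pre <- NULL
  recurse <- function(supp, delta, rel, check) {
    if ("primal" %in% check && !relax_primal_ok(rb, system, supp, delta,
                                                 lite = TRUE))
      return(invisible())
    if ("dual" %in% check && !relax_dual_ok(rb, system, supp, delta,
                                            prebuilt = dual_pre))
      return(invisible())
    j <- rel[is.na(delta[rel])]
    if (!length(j)) {
      # full check before the (much more expensive) leaf solve; deferred
      # strict-slack rows are validated here at the latest
      if (relax_primal_ok(rb, system, supp, delta) &&
          relax_dual_ok(rb, system, supp, delta, prebuilt = dual_pre))
        solve_leaf(supp, delta)
      return(invisible())
    }
    j <- j[1L]
    kind <- system$pair_kind[j]
    for (v in c(1L, 0L)) {
      d2 <- delta; d2[j] <- v
      # inactive caps add only the strict-slack row, whose effect is
      # picked up by the next primal check; re-check the dual side now
      chk <- if (v == 1L) "primal"
             else if (kind == "Cnn") "primal" else "dual"
      recurse(supp, d2, rel, chk)
    }
    invisible()
  }

  supports <- as.matrix(expand.grid(rep(list(c(1L, 0L)), n_X)))
  for (r in seq_len(nrow(supports))) {
    supp <- as.integer(supports[r, ])
    rel_cap <- which(system$pair_kind == "cap" &
                       system$sp_of_Arow[system$pair_ref] %in% which(supp == 1L))
    rel_glob <- which(system$pair_kind %in% c("Cnn", "culture"))
    # decide the global concentration-sign / culture pairs first: they
    # constrain every species subtree
    rel <- c(rel_glob, rel_cap)
    delta <- rep(NA_integer_, n_l1)
    keep <- which(supp == 1L)
    dual_pre <- if (length(keep)) {
      blocks <- lapply(keep, rb$dual_block)
      list(A = do.call(rbind, lapply(blocks, `[[`, "A")),
           b = unlist(lapply(blocks, `[[`, "b")))
    }
    if (!relax_primal_ok(rb, system, supp, delta) ||
        !relax_dual_ok(rb, system, supp, delta, prebuilt = dual_pre)) next
    # unit propagation: fix every pair whose alternative branch is
    # already infeasible before descending (each fixed bit halves the
    # subtree)
    dead <- FALSE
    for (pass in 1:2) {
      changed <- FALSE
      for (j in rel[is.na(delta[rel])]) {
        ok <- logical(2)
        for (v in c(1L, 0L)) {
          d2 <- delta; d2[j] <- v
          ok[v + 1L] <- relax_primal_ok(rb, system, supp, d2) &&
            relax_dual_ok(rb, system, supp, d2, prebuilt = dual_pre)
        }
        if (!any(ok)) { dead <- TRUE; break }
        if (xor(ok[1L], ok[2L])) {
          delta[j] <- if (ok[2L]) 1L else 0L
          changed <- TRUE
        }
      }
      if (dead || !changed) break
    }
    if (dead) next
    recurse(supp, delta, rel, "none")
  }

  keep <- Filter(function(s) {
    s$residual_max < threshold &&
      verify_inner_optimality(model, env, s) < 1e-6
  }, sols)
  keep <- dedupe_solutions(keep, tol = dedupe_tol)
  ab <- lapply(keep, function(s) if (!is.null(s$X)) s$X else s$x)
  if (length(keep) > 1L) {
    ord <- do.call(order, as.data.frame(do.call(rbind, ab)))
    keep <- keep[ord]
  }
  keep
}
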
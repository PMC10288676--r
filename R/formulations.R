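# Assembly of the steady-state algebraic systems.
#
# For each (model, environment, mode) the community steady-state problem
# is a system of outer stationarity conditions plus the KKT conditions of
# an inner linear program (growth maximisation per species for the agent
# modes, community biomass production or summed growth for the community
# modes). Because the inner problems are linear, KKT is sufficient for
# global optimality, and the steady states are exactly the zeros of the
# assembled system subject to its inequalities.
#
# Variable layout (one flat vector z):
#   chemostat: [nu_1 .. nu_nX | C | X | lambda1 | lambda2]
#   batch:     [nu_1 .. nu_nX | x | mu_star | lambda1 | lambda2]
# lambda1 stacks the capacity-row multipliers species by species, then
# (CC) the C >= 0 multipliers or (BC) the culture-bound multipliers.
# lambda2 stacks the intracellular balance multipliers, then (CC) the
# chemostat mass-balance multipliers.

support_threshold <- 1e-9

#' Assemble the algebraic steady-state system
#'
#' Builds the full equation system (outer stationarity, inner KKT
#' stationarity, complementary slackness in multiplicative form) and the
#' inequality set for a model/environment pair. The returned object owns
#' the variable layout and residual closures used by [residual()], the
#' grid stage and the refinement stage.
#'
#' @param model a validated [community_model()].
#' @param env an [environment_spec()].
#' @return object of class `algebraic_system` with elements `layout`
#'   (named index slices into the variable vector), `eq(z)`, `ineq(z)`
#'   (convention `g(z) <= 0`), `eq_names`, `ineq_names`, `n_z`, and the
#'   assembled coefficient blocks.
#' @export
assemble_system <- function(model, env) {
  diag <- validate_community(model)
  if (length(diag)) stop("invalid community model: ", paste(diag, collapse = "; "))
  mode <- env$mode
  chemostat <- mode %in% c("CA", "CC")
  community <- mode %in% c("CC", "BC")
  if (!community && !is.null(env$objective))
    stop("agent modes carry no objective")
  n_X <- length(model$species)
  n_C <- length(model$extracellular_ids)
  sp_ids <- vapply(model$species, `[[`, "", "id")
  nnu <- vapply(model$species, function(s) length(s$reaction_ids), 1L)
  nu_off <- cumsum(c(0L, nnu))[seq_len(n_X)]
  nnu_tot <- sum(nnu)
  nS <- vapply(model$species, function(s) nrow(s$S), 1L)
  nA <- vapply(model$species, function(s) nrow(s$A), 1L)

  if (!chemostat) {
    dep <- unlist(lapply(model$species, function(s)
      vapply(s$b, Negate(is_constant_bound), TRUE)))
    if (any(dep))
      stop("batch modes require constant bounds; model has ",
           "concentration-dependent bound specs")
  }

  blkdiag <- function(mats) {
    nr <- vapply(mats, nrow, 1L); nc <- vapply(mats, ncol, 1L)
    M <- matrix(0, sum(nr), sum(nc))
    ro <- cumsum(c(0L, nr)); co <- cumsum(c(0L, nc))
    for (i in seq_along(mats)) {
      M[ro[i] + seq_len(nr[i]), co[i] + seq_len(nc[i])] <- mats[[i]]
    }
    M
  }
  Sblk <- blkdiag(lapply(model$species, `[[`, "S"))
  Ablk <- blkdiag(lapply(model$species, `[[`, "A"))
  Tcat <- do.call(cbind, lapply(model$species, `[[`, "T"))
  bounds <- unlist(lapply(model$species, `[[`, "b"), recursive = FALSE)
  sp_of_Arow <- rep(seq_len(n_X), nA)
  g_idx <- nu_off + vapply(model$species, `[[`, 1L, "growth_index")

  # ---- layout ----------------------------------------------------------
  pos <- 0L
  take <- function(k) { idx <- pos + seq_len(k); pos <<- pos + k; idx }
  lay <- list(nu = lapply(seq_len(n_X), function(i) nu_off[i] + seq_len(nnu[i])))
  pos <- nnu_tot
  lay$nu_all <- seq_len(nnu_tot)
  if (chemostat) {
    lay$C <- take(n_C)
    lay$X <- take(n_X)
  } else {
    lay$x <- take(n_X)
    lay$mu_star <- take(1L)
  }
  lay$l1A <- take(sum(nA))
  if (mode == "CC") lay$l1C <- take(n_C)
  if (mode == "BC") lay$l1u <- take(n_C)
  lay$l2S <- take(sum(nS))
  if (mode == "CC") lay$l2C <- take(n_C)
  lay$l1 <- c(lay$l1A, lay$l1C, lay$l1u)
  lay$l2 <- c(lay$l2S, lay$l2C)
  n_z <- pos
  l1A_of_sp <- split(seq_len(sum(nA)), sp_of_Arow)
  l2S_of_sp <- split(seq_len(sum(nS)), rep(seq_len(n_X), nS))

  ext <- model$extracellular_ids
  rxn_names <- unlist(lapply(seq_len(n_X), function(i)
    paste(sp_ids[i], model$species[[i]]$reaction_ids, sep = ".")))
  arow_names <- unlist(lapply(seq_len(n_X), function(i)
    paste0(sp_ids[i], ".cap", seq_len(nA[i]))))
  srow_names <- unlist(lapply(seq_len(n_X), function(i)
    paste(sp_ids[i], model$species[[i]]$metabolite_ids, sep = ".")))

  # multiplier-pair bookkeeping: q_j for the j-th lambda1 component
  pair_kind <- c(rep("cap", sum(nA)),
                 if (mode == "CC") rep("Cnn", n_C),
                 if (mode == "BC") rep("culture", n_C))
  pair_ref <- c(seq_len(sum(nA)),
                if (mode %in% c("CC", "BC")) seq_len(n_C))

  eq_names <- c(
    if (chemostat) paste0("massbal.", ext),
    if (chemostat) paste0("dgrowth.", sp_ids),
    if (!chemostat) paste0("growth_tie.", sp_ids),
    if (!chemostat) "sumx",
    paste0("intracell.", srow_names),
    paste0("stat.", rxn_names),
    if (mode == "CC") paste0("statC.", ext),
    paste0("compl.", c(arow_names,
                       if (mode == "CC") paste0("Cnn.", ext),
                       if (mode == "BC") paste0("culture.", ext)))
  )
  ineq_names <- c(
    paste0("cap.", arow_names),
    if (chemostat) paste0("Cnn.", ext),
    if (chemostat) paste0("Xnn.", sp_ids),
    if (!chemostat) paste0("culture.", ext),
    if (!chemostat) paste0("xnn.", sp_ids),
    paste0("l1nn.", seq_along(lay$l1))
  )

  objective <- env$objective
  obj_weight <- function(ab) {
    if (!community || identical(objective, "biomass_production")) ab
    else as.numeric(ab > support_threshold)
  }

  total_exchange <- function(nu_vec, ab) {
    # sum_i T_i nu_i ab_i over species
    acc <- numeric(n_C)
    for (i in seq_len(n_X)) {
      sp <- model$species[[i]]
      acc <- acc + as.vector(sp$T %*% nu_vec[lay$nu[[i]]]) * ab[i]
    }
    acc
  }

  eq_fun <- function(z, piece_choice = NULL) {
    nu <- z[lay$nu_all]
    l1A <- z[lay$l1A]; l2S <- z[lay$l2S]
    out <- numeric(0)
    if (chemostat) {
      C <- z[lay$C]; X <- z[lay$X]
      bC <- evaluate_bounds(bounds, C)
      out <- c(out, env$D * (env$C_in - C) - total_exchange(z, X))
      out <- c(out, X * (env$D - nu[g_idx]))
      out <- c(out, as.vector(Sblk %*% nu))
      w <- obj_weight(X)
      stat <- numeric(nnu_tot)
      for (i in seq_len(n_X)) {
        sp <- model$species[[i]]
        s <- crossprod(sp$A, l1A[l1A_of_sp[[i]]]) +
          crossprod(sp$S, l2S[l2S_of_sp[[i]]])
        s <- as.vector(s)
        if (mode == "CA") {
          s[sp$growth_index] <- s[sp$growth_index] - 1
        } else {
          s[sp$growth_index] <- s[sp$growth_index] - w[i]
          s <- s - X[i] * as.vector(crossprod(sp$T, z[lay$l2C]))
        }
        stat[lay$nu[[i]]] <- s
      }
      out <- c(out, stat)
      if (mode == "CC") {
        G <- bound_gradient(bounds, C, piece_choice)
        out <- c(out, as.vector(-crossprod(G, l1A)) - z[lay$l1C] -
                   env$D * z[lay$l2C])
      }
      qA <- as.vector(Ablk %*% nu) - bC
      comp <- l1A * qA
      if (mode == "CC") comp <- c(comp, z[lay$l1C] * (-C))
      out <- c(out, comp)
    } else {
      x <- z[lay$x]; ms <- z[lay$mu_star]
      bC <- evaluate_bounds(bounds, rep(0, n_C)) # constant by construction
      out <- c(out, x * (ms - nu[g_idx]))
      out <- c(out, sum(x) - 1)
      out <- c(out, as.vector(Sblk %*% nu))
      w <- obj_weight(x)
      stat <- numeric(nnu_tot)
      for (i in seq_len(n_X)) {
        sp <- model$species[[i]]
        s <- crossprod(sp$A, l1A[l1A_of_sp[[i]]]) +
          crossprod(sp$S, l2S[l2S_of_sp[[i]]])
        s <- as.vector(s)
        if (mode == "BA") {
          s[sp$growth_index] <- s[sp$growth_index] - 1
        } else {
          s[sp$growth_index] <- s[sp$growth_index] - w[i]
          s <- s + x[i] * as.vector(crossprod(sp$T, z[lay$l1u]))
        }
        stat[lay$nu[[i]]] <- s
      }
      out <- c(out, stat)
      qA <- as.vector(Ablk %*% nu) - bC
      comp <- l1A * qA
      if (mode == "BC") {
        qu <- total_exchange(z, x) - env$u
        comp <- c(comp, z[lay$l1u] * qu)
      }
      out <- c(out, comp)
    }
    names(out) <- eq_names
    out
  }

  ineq_fun <- function(z) {
    nu <- z[lay$nu_all]
    out <- numeric(0)
    if (chemostat) {
      C <- z[lay$C]
      bC <- evaluate_bounds(bounds, C)
      out <- c(out, as.vector(Ablk %*% nu) - bC, -C, -z[lay$X])
    } else {
      bC <- evaluate_bounds(bounds, rep(0, n_C))
      out <- c(out, as.vector(Ablk %*% nu) - bC,
               total_exchange(z, z[lay$x]) - env$u, -z[lay$x])
    }
    out <- c(out, -z[lay$l1])
    names(out) <- ineq_names
    out
  }

  structure(list(
    mode = mode, objective = objective, model = model, env = env,
    n_X = n_X, n_C = n_C, nnu = nnu, nu_off = nu_off, nS = nS, nA = nA,
    g_idx = g_idx, Sblk = Sblk, Ablk = Ablk, Tcat = Tcat, bounds = bounds,
    sp_of_Arow = sp_of_Arow, l1A_of_sp = l1A_of_sp, l2S_of_sp = l2S_of_sp,
    pair_kind = pair_kind, pair_ref = pair_ref,
    layout = lay, n_z = n_z, sp_ids = sp_ids,
    eq = eq_fun, ineq = ineq_fun,
    eq_names = eq_names, ineq_names = ineq_names
  ), class = "algebraic_system")
}

#' @export
print.algebraic_system <- function(x, ...) {
  cat(sprintf("algebraic_system (%s%s): %d variables, %d equalities, %d inequalities\n",
              x$mode,
              if (!is.null(x$objective)) paste0(", ", x$objective) else "",
              x$n_z, length(x$eq_names), length(x$ineq_names)))
  invisible(x)
}

#' Pack a solution into the system's variable vector
#' @param system an `algebraic_system`.
#' @param sol a [steady_state_solution()].
#' @return numeric vector of length `system$n_z`.
#' @export
solution_to_z <- function(system, sol) {
  z <- numeric(system$n_z)
  lay <- system$layout
  for (i in seq_len(system$n_X)) z[lay$nu[[i]]] <- sol$nu[[i]]
  if (!is.null(lay$C)) z[lay$C] <- sol$C
  if (!is.null(lay$X)) z[lay$X] <- sol$X
  if (!is.null(lay$x)) z[lay$x] <- sol$x
  if (!is.null(lay$mu_star)) z[lay$mu_star] <- sol$mu_star
  if (!is.null(sol$lambda1)) z[lay$l1] <- sol$lambda1
  if (!is.null(sol$lambda2)) z[lay$l2] <- sol$lambda2
  z
}

#' Unpack a variable vector into a solution object
#' @inheritParams solution_to_z
#' @param z numeric vector of length `system$n_z`.
#' @param branch optional pattern metadata to attach.
#' @return a [steady_state_solution()] with residual diagnostics filled in.
#' @export
z_to_solution <- function(system, z, branch = NULL) {
  lay <- system$layout
  zap <- function(v) { v[abs(v) < 1e-12] <- 0; v }
  z <- zap(z)
  nu <- lapply(seq_len(system$n_X), function(i) {
    v <- z[lay$nu[[i]]]
    names(v) <- system$model$species[[i]]$reaction_ids
    v
  })
  names(nu) <- system$sp_ids
  sol <- steady_state_solution(
    nu = nu,
    C = if (!is.null(lay$C)) stats::setNames(z[lay$C], system$model$extracellular_ids),
    X = if (!is.null(lay$X)) stats::setNames(z[lay$X], system$sp_ids),
    x = if (!is.null(lay$x)) stats::setNames(z[lay$x], system$sp_ids),
    mu_star = if (!is.null(lay$mu_star)) z[lay$mu_star],
    lambda1 = z[lay$l1], lambda2 = z[lay$l2], branch = branch)
  rep <- residual(system, sol)
  sol$residual_max <- rep$residual_max
  sol$residual_ssq <- rep$residual_ssq
  sol
}

# enumerate piece-choice combinations over bounds whose minimum is tied at C
tied_piece_choices <- function(system, C, tie_tol = 1e-9, max_combos = 64L) {
  opts <- lapply(system$bounds, function(spec) {
    vals <- vapply(spec$pieces, function(p) p$intercept + sum(p$gradient * C), 0)
    which(vals <= min(vals) + tie_tol)
  })
  n_comb <- prod(vapply(opts, length, 1L))
  if (n_comb == 1 || n_comb > max_combos) {
    return(list(vapply(opts, `[`, 1L, 1L)))
  }
  grid <- do.call(expand.grid, opts)
  lapply(seq_len(nrow(grid)), function(r) as.integer(grid[r, ]))
}

#' Residuals of a candidate solution
#'
#' Exact evaluation, no tolerance applied: equality residuals enter as
#' absolute values, inequality contributions as `max(0, violation)`. At
#' a kink of a piecewise-linear bound, the stationarity rows are scored
#' with the adjacent piece gradients and the best combination is
#' reported (subgradient selection).
#'
#' @param system an [assemble_system()] result.
#' @param cand a [steady_state_solution()] dimensionally matching the
#'   system layout.
#' @return object of class `residual_report`: `residual_max`,
#'   `residual_ssq`, and `breakdown` (named per-equation values).
#' @export
residual <- function(system, cand) {
  z <- if (is.numeric(cand)) cand else solution_to_z(system, cand)
  choices <- if (system$mode == "CC")
    tied_piece_choices(system, z[system$layout$C]) else list(NULL)
  best <- NULL
  for (pc in choices) {
    eqv <- system$eq(z, piece_choice = pc)
    inv <- pmax(0, system$ineq(z))
    all_v <- c(abs(eqv), inv)
    rmax <- if (length(all_v)) max(all_v) else 0
    if (is.null(best) || rmax < best$residual_max) {
      best <- structure(list(residual_max = rmax,
                             residual_ssq = sum(all_v^2),
                             breakdown = c(eqv, inv)),
                        class = "residual_report")
    }
  }
  best
}

#' @export
print.residual_report <- function(x, ...) {
  cat(sprintf("residual_report: max %.3g, ssq %.3g\n",
              x$residual_max, x$residual_ssq))
  worst <- sort(abs(x$breakdown), decreasing = TRUE)
  worst <- worst[worst > 0][seq_len(min(5, sum(worst > 0)))]
  if (length(worst)) {
    cat("  largest contributions:\n")
    for (nm in names(worst)) cat(sprintf("    %s: %.3g\n", nm, worst[[nm]]))
  }
  invisible(x)
}

# expand piecewise bounds into LP rows over (nu, C): A_j nu - grad_p C <= int_p
capacity_lp_rows <- function(system, with_C) {
  nA_tot <- length(system$bounds)
  nnu_tot <- sum(system$nnu)
  rows <- list(); rhs <- numeric(0)
  for (j in seq_len(nA_tot)) {
    for (p in system$bounds[[j]]$pieces) {
      r <- c(system$Ablk[j, ], if (with_C) -p$gradient)
      rows[[length(rows) + 1L]] <- r
      rhs <- c(rhs, p$intercept)
    }
  }
  list(A = do.call(rbind, rows), b = rhs)
}

#' Certify inner-problem optimality of a candidate
#'
#' Solves the inner linear program directly at the candidate's fixed
#' outer variables (CA/BA: per species at fixed concentrations; CC:
#' jointly over fluxes and concentrations at fixed abundances; BC:
#' jointly over fluxes at fixed relative abundances) and returns the
#' optimality gap `LP optimum - candidate's inner objective value`. A
#' gap below tolerance certifies inner optimality independently of the
#' multipliers.
#'
#' @param model a [community_model()].
#' @param env an [environment_spec()].
#' @param cand a [steady_state_solution()], feasible for the inner
#'   problem within `tol`.
#' @param tol feasibility slack granted to the candidate.
#' @return non-negative optimality gap (`Inf` if the inner problem is
#'   unbounded at the candidate's outer variables).
#' @export
verify_inner_optimality <- function(model, env, cand, tol = 1e-6) {
  system <- assemble_system(model, env)
  mode <- env$mode
  n_C <- system$n_C
  if (mode %in% c("CA", "BA")) {
    gaps <- vapply(seq_len(system$n_X), function(i) {
      sp <- model$species[[i]]
      n_nu <- ncol(sp$S)
      Cfix <- if (mode == "CA") cand$C else rep(0, n_C)
      bC <- evaluate_bounds(sp$b, Cfix)
      obj <- numeric(n_nu); obj[sp$growth_index] <- 1
      res <- solve_lp(obj, A_ub = sp$A, b_ub = bC,
                      A_eq = sp$S, b_eq = rep(0, nrow(sp$S)),
                      maximize = TRUE)
      if (res$status == "unbounded") return(Inf)
      if (res$status != "optimal") stop("inner LP failed for species ",
                                        sp$id, ": ", res$status)
      res$value - cand$nu[[i]][sp$growth_index]
    }, 0)
    return(max(0, max(gaps)))
  }
  nnu_tot <- sum(system$nnu)
  ab <- if (mode == "CC") cand$X else cand$x
  w <- if (identical(env$objective, "sum_growth"))
    as.numeric(ab > support_threshold) else ab
  obj <- numeric(nnu_tot + if (mode == "CC") n_C else 0L)
  obj[system$g_idx] <- w
  if (mode == "CC") {
    cap <- capacity_lp_rows(system, with_C = TRUE)
    # mass balance at fixed X: D C_in - D C - sum_i X_i T_i nu_i = 0
    Tw <- system$Tcat * rep(ab, system$nnu)[col(system$Tcat)]
    A_eq <- rbind(cbind(Tw, diag(env$D, n_C)),
                  cbind(system$Sblk, matrix(0, nrow(system$Sblk), n_C)))
    b_eq <- c(env$D * env$C_in, rep(0, nrow(system$Sblk)))
    lower <- c(rep(-Inf, nnu_tot), rep(0, n_C))
    res <- solve_lp(obj, A_ub = cap$A, b_ub = cap$b,
                    A_eq = A_eq, b_eq = b_eq, lower = lower,
                    maximize = TRUE)
    cand_val <- sum(w * vapply(seq_len(system$n_X), function(i)
      cand$nu[[i]][model$species[[i]]$growth_index], 0))
  } else { # BC
    cap <- capacity_lp_rows(system, with_C = FALSE)
    Tw <- system$Tcat * rep(ab, system$nnu)[col(system$Tcat)]
    res <- solve_lp(obj, A_ub = rbind(cap$A, Tw),
                    b_ub = c(cap$b, env$u),
                    A_eq = system$Sblk, b_eq = rep(0, nrow(system$Sblk)),
                    maximize = TRUE)
    cand_val <- sum(w * vapply(seq_len(system$n_X), function(i)
      cand$nu[[i]][model$species[[i]]$growth_index], 0))
  }
  if (res$status == "unbounded") return(Inf)
  if (res$status != "optimal") stop("inner LP failed: ", res$status)
  max(0, res$value - cand_val)
}
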
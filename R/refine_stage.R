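# Second numerical stage: Levenberg-Marquardt refinement of grid
# candidates, acceptance filtering and deduplication.

#' Refinement and acceptance settings
#'
#' @param threshold acceptance threshold on the maximal constraint
#'   violation (a feasible, globally optimal steady state must have a
#'   virtually zero residual).
#' @param max_iter Levenberg-Marquardt iteration cap.
#' @param ftol,ptol relative convergence tolerances passed to the
#'   optimiser.
#' @param dedupe_tol deduplication tolerance in abundance/concentration
#'   space.
#' @return object of class `refinement_settings`.
#' @export
refinement_settings <- function(threshold = 1e-8, max_iter = 200,
                                ftol = 1e-15, ptol = 1e-15,
                                dedupe_tol = 1e-6) {
  stopifnot(threshold > 0, max_iter > 0, ftol > 0, ptol > 0, dedupe_tol > 0)
  structure(list(threshold = threshold, max_iter = max_iter,
                 ftol = ftol, ptol = ptol, dedupe_tol = dedupe_tol),
            class = "refinement_settings")
}

#' Refine a candidate by least-squares residual minimisation
#'
#' Minimises the sum of squares of all constraint violations (equality
#' residuals, hinge terms `max(0, violation)` for the inequalities, and
#' the multiplicative complementarity products) with the
#' Levenberg-Marquardt algorithm. All variables, including the
#' abundances, are free during refinement, so candidates may migrate
#' away from their grid point; non-negativity of abundances,
#' concentrations and inequality multipliers is enforced through box
#' constraints.
#'
#' @param system an [assemble_system()] result.
#' @param start a [steady_state_solution()] (dimensionally valid).
#' @param settings a [refinement_settings()].
#' @return refined [steady_state_solution()]; its `residual_ssq` never
#'   exceeds the start's.
#' @export
refine <- function(system, start, settings = refinement_settings()) {
  z0 <- solution_to_z(system, start)
  lay <- system$layout
  resid_vec <- function(z) c(system$eq(z), pmax(0, system$ineq(z)))
  f0 <- resid_vec(z0)
  if (any(!is.finite(f0))) stop("non-finite residual at start")
  if (all(z0[c(lay$l1, lay$l2)] == 0) && length(lay$l1)) {
    # candidates without multipliers (e.g. tabulated fluxes): seed the
    # multipliers by least squares on the KKT stationarity rows at the
    # given primal point, clipping the inequality multipliers to >= 0
    lam_idx <- c(lay$l1, lay$l2)
    stat_rows <- grep("^stat", system$eq_names)
    base <- system$eq(z0)[stat_rows]
    Jl <- vapply(seq_along(lam_idx), function(k) {
      zp <- z0; zp[lam_idx[k]] <- 1
      system$eq(zp)[stat_rows] - base
    }, numeric(length(stat_rows)))
    fit <- tryCatch(qr.coef(qr(Jl), -base), error = function(e) NULL)
    if (!is.null(fit)) {
      fit[is.na(fit)] <- 0
      z0[lam_idx] <- fit
      z0[lay$l1] <- pmax(z0[lay$l1], 0)
    }
  }
  lower <- rep(-Inf, system$n_z)
  if (!is.null(lay$C)) lower[lay$C] <- 0
  if (!is.null(lay$X)) lower[lay$X] <- 0
  if (!is.null(lay$x)) lower[lay$x] <- 0
  lower[lay$l1] <- 0
  z0 <- pmax(z0, lower)
  ctrl <- minpack.lm::nls.lm.control(
    maxiter = settings$max_iter, ftol = settings$ftol,
    ptol = settings$ptol, maxfev = 100000)
  # stage 1: settle fluxes and multipliers at the start's abundances, so
  # the candidate stays in the basin it seeds; stage 2 releases the
  # abundances and lets the candidate migrate off its grid point
  ab_idx <- c(lay$X, lay$x)
  free <- setdiff(seq_len(system$n_z), ab_idx)
  fit1 <- minpack.lm::nls.lm(
    par = z0[free],
    fn = function(v) { z <- z0; z[free] <- v; resid_vec(z) },
    lower = lower[free], control = ctrl)
  z0[free] <- fit1$par
  fit <- minpack.lm::nls.lm(
    par = z0, fn = resid_vec, lower = lower, control = ctrl)
  z1 <- fit$par
  out <- z_to_solution(system, z1, branch = start$branch)
  start_ssq <- sum(resid_vec(solution_to_z(system, start))^2)
  if (out$residual_ssq > start_ssq) {
    out <- z_to_solution(system, solution_to_z(system, start),
                         branch = start$branch)
  }
  out
}

#' Acceptance filter for candidate solutions
#'
#' Keeps exactly the candidates whose maximal constraint violation is
#' below the acceptance threshold and whose inner linear program is
#' certified optimal by an independent LP solve
#' ([verify_inner_optimality()] gap below `1e-6`).
#'
#' @param cands list of [steady_state_solution()] objects.
#' @param model,env the community model and environment they refer to.
#' @param settings a [refinement_settings()].
#' @return filtered list.
#' @export
accept_solutions <- function(cands, model, env,
                             settings = refinement_settings()) {
  Filter(function(s) {
    is.finite(s$residual_max) && s$residual_max < settings$threshold &&
      verify_inner_optimality(model, env, s) < 1e-6
  }, cands)
}

#' Deduplicate solutions in abundance/concentration space
#'
#' Groups solutions whose concatenated abundance and concentration
#' vectors (batch: relative abundances and community growth rate) agree
#' within `tol` in the infinity norm, keeping the representative with
#' the lowest maximal residual.
#'
#' @param sols list of [steady_state_solution()] objects.
#' @param tol merge tolerance.
#' @return list of representatives (input order preserved).
#' @export
dedupe_solutions <- function(sols, tol = 1e-6) {
  if (length(sols) <= 1L) return(sols)
  key <- lapply(sols, function(s) {
    c(if (!is.null(s$X)) s$X else s$x,
      if (!is.null(s$C)) s$C else s$mu_star)
  })
  reps <- list(); rep_keys <- list()
  for (k in seq_along(sols)) {
    hit <- 0L
    for (r in seq_along(rep_keys)) {
      if (max(abs(key[[k]] - rep_keys[[r]])) <= tol) { hit <- r; break }
    }
    if (hit == 0L) {
      reps[[length(reps) + 1L]] <- sols[[k]]
      rep_keys[[length(rep_keys) + 1L]] <- key[[k]]
    } else if (sols[[k]]$residual_max < reps[[hit]]$residual_max) {
      reps[[hit]] <- sols[[k]]
    }
  }
  reps
}
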
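# Domain types: species networks, communities, environments, solutions.
#
# Sign conventions, fixed throughout the package:
#   * `T %*% nu` positive  = net uptake of an extracellular compound
#     (the chemostat balance reads dC/dt = D*(C_in - C) - sum_i T_i nu_i X_i);
#   * reporting via `net_exchange()` flips the sign to secretion-positive.
# All quantities are in consistent arbitrary units; nothing is converted.

#' Piecewise-linear concave flux bound
#'
#' A capacity-constraint right-hand side, possibly dependent on the
#' extracellular concentrations `C`. The effective bound is the minimum
#' over affine pieces `intercept + gradient %*% C`, hence piecewise-linear
#' and concave in `C`. Constant bounds are a single piece with zero
#' gradient.
#'
#' @param pieces list of pieces, each a list with numeric scalars/vectors
#'   `intercept` and `gradient` (gradient length = number of extracellular
#'   compounds).
#' @return object of class `bound_spec`.
#' @seealso [constant_bound()], [evaluate_bounds()]
#' @export
bound_spec <- function(pieces) {
  stopifnot(is.list(pieces), length(pieces) >= 1L)
  pieces <- lapply(pieces, function(p) {
    stopifnot(is.numeric(p$intercept), length(p$intercept) == 1L,
              is.numeric(p$gradient))
    list(intercept = as.numeric(p$intercept), gradient = as.numeric(p$gradient))
  })
  structure(list(pieces = pieces), class = "bound_spec")
}

#' @rdname bound_spec
#' @param value constant bound value.
#' @param n_C number of extracellular compounds (gradient length).
#' @export
constant_bound <- function(value, n_C) {
  bound_spec(list(list(intercept = value, gradient = rep(0, n_C))))
}

is_constant_bound <- function(b) {
  all(vapply(b$pieces, function(p) all(p$gradient == 0), TRUE))
}

#' Single-organism metabolic network
#'
#' Stoichiometry, capacity constraints and exchange map of one community
#' member. Rows of `A` flagged in `uptake_rows` may carry
#' concentration-dependent bounds; all other rows must be constant.
#'
#' @param id species identifier (unique within a community).
#' @param metabolite_ids intracellular metabolite names (rows of `S`).
#' @param reaction_ids reaction names (columns of `S`, `A`, `T`).
#' @param S stoichiometric matrix (n_S x n_nu).
#' @param A capacity constraint matrix (n_A x n_nu); `A nu <= b(C)`.
#' @param b list of `n_A` [bound_spec()] objects.
#' @param T exchange map (n_C x n_nu); positive `T nu` = net uptake.
#' @param growth_index column index of the growth reaction in `S`.
#' @param uptake_rows rows of `A` that represent uptake capacity and may
#'   depend on `C`; defaults to the rows with non-constant bounds.
#' @return object of class `species_network`.
#' @export
species_network <- function(id, metabolite_ids, reaction_ids, S, A, b, T,
                            growth_index, uptake_rows = NULL) {
  S <- as.matrix(S); A <- as.matrix(A); T <- as.matrix(T)
  if (is.null(uptake_rows)) {
    uptake_rows <- which(!vapply(b, is_constant_bound, TRUE))
  }
  obj <- structure(list(
    id = as.character(id),
    metabolite_ids = as.character(metabolite_ids),
    reaction_ids = as.character(reaction_ids),
    S = S, A = A, b = b, T = T,
    growth_index = as.integer(growth_index),
    uptake_rows = as.integer(uptake_rows)
  ), class = "species_network")
  obj
}

#' Community of species sharing one extracellular compound set
#'
#' @param species list of [species_network()] objects.
#' @param extracellular_ids names of the shared extracellular compounds
#'   (rows of every species' `T`).
#' @return object of class `community_model`.
#' @export
community_model <- function(species, extracellular_ids) {
  structure(list(species = species,
                 extracellular_ids = as.character(extracellular_ids)),
            class = "community_model")
}

#' @export
print.community_model <- function(x, ...) {
  cat(sprintf("community_model: %d species, %d extracellular compounds\n",
              length(x$species), length(x$extracellular_ids)))
  for (sp in x$species) {
    cat(sprintf("  %s: %d metabolites, %d reactions, %d capacity rows\n",
                sp$id, nrow(sp$S), ncol(sp$S), nrow(sp$A)))
  }
  invisible(x)
}

#' Environment and decision-making specification
#'
#' The four model variants combine the cultivation environment (chemostat
#' `C*` with dilution rate `D` and inflow `C_in`; steady-state batch `B*`
#' with culture uptake bounds `u`) with the decision maker (`*A` rational
#' agent: each species maximises its own growth; `*C` rational community:
#' a community-level optimiser).
#'
#' @param mode one of `"CA"`, `"CC"`, `"BA"`, `"BC"`.
#' @param D dilution rate (chemostat modes), 1/time.
#' @param C_in inflow concentration vector (chemostat modes).
#' @param u culture uptake bound vector (batch modes).
#' @param objective community objective, `"biomass_production"`
#'   (`sum nu_mu,i X_i`) or `"sum_growth"` (`sum nu_mu,i` over the
#'   declared support); community modes only.
#' @return object of class `environment_spec`.
#' @export
environment_spec <- function(mode, D = NULL, C_in = NULL, u = NULL,
                             objective = NULL) {
  mode <- match.arg(mode, c("CA", "CC", "BA", "BC"))
  chemostat <- mode %in% c("CA", "CC")
  community <- mode %in% c("CC", "BC")
  if (chemostat) {
    if (is.null(D) || is.null(C_in) || !is.null(u))
      stop("chemostat modes require D and C_in and no u")
    if (D <= 0) stop("D must be positive")
    if (any(C_in < 0)) stop("C_in must be non-negative")
  } else {
    if (is.null(u) || !is.null(D) || !is.null(C_in))
      stop("batch modes require u and neither D nor C_in")
  }
  if (community) {
    if (is.null(objective)) objective <- "biomass_production"
    objective <- match.arg(objective, c("biomass_production", "sum_growth"))
  } else if (!is.null(objective)) {
    stop("agent modes carry no objective")
  }
  structure(list(mode = mode, D = D, C_in = C_in, u = u,
                 objective = objective),
            class = "environment_spec")
}

#' Candidate or accepted steady-state solution
#'
#' @param nu list of per-species flux vectors.
#' @param C extracellular concentrations (chemostat modes).
#' @param X absolute abundances (chemostat) or `x` relative abundances
#'   (batch, summing to one).
#' @param x relative abundances (batch modes).
#' @param mu_star community growth rate (batch modes).
#' @param lambda1,lambda2 inequality / equality multipliers.
#' @param residual_max,residual_ssq residual diagnostics (see
#'   [residual()]).
#' @param branch optional complementarity pattern metadata.
#' @return object of class `steady_state_solution`.
#' @export
steady_state_solution <- function(nu, C = NULL, X = NULL, x = NULL,
                                  mu_star = NULL, lambda1 = NULL,
                                  lambda2 = NULL, residual_max = NA_real_,
                                  residual_ssq = NA_real_, branch = NULL) {
  structure(list(nu = nu, C = C, X = X, x = x, mu_star = mu_star,
                 lambda1 = lambda1, lambda2 = lambda2,
                 residual_max = residual_max, residual_ssq = residual_ssq,
                 branch = branch),
            class = "steady_state_solution")
}

#' @export
print.steady_state_solution <- function(x, ...) {
  ab <- if (!is.null(x$X)) x$X else x$x
  cat("steady_state_solution\n")
  cat("  abundances:", paste(signif(ab, 4), collapse = " "), "\n")
  if (!is.null(x$C)) cat("  C:", paste(signif(x$C, 4), collapse = " "), "\n")
  if (!is.null(x$mu_star)) cat("  mu*:", signif(x$mu_star, 4), "\n")
  cat("  residual_max:", format(x$residual_max), "\n")
  invisible(x)
}

#' Validate a community model
#'
#' Checks all structural invariants (matrix dimensions, growth index in
#' range, bound gradients matching the extracellular compound count,
#' unique species ids, constant bounds outside uptake rows) and returns
#' diagnostics instead of raising conditions.
#'
#' @param model a [community_model()].
#' @return character vector of human-readable diagnostics; empty when all
#'   invariants hold.
#' @export
validate_community <- function(model) {
  out <- character(0)
  n_C <- length(model$extracellular_ids)
  ids <- vapply(model$species, function(s) s$id, "")
  if (anyDuplicated(ids))
    out <- c(out, sprintf("duplicate species ids: %s",
                          paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  for (sp in model$species) {
    n_nu <- length(sp$reaction_ids)
    if (ncol(sp$S) != n_nu || nrow(sp$S) != length(sp$metabolite_ids))
      out <- c(out, sprintf("%s: S is %dx%d, expected %dx%d", sp$id,
                            nrow(sp$S), ncol(sp$S),
                            length(sp$metabolite_ids), n_nu))
    if (ncol(sp$A) != n_nu)
      out <- c(out, sprintf("%s: A has %d columns, expected %d", sp$id,
                            ncol(sp$A), n_nu))
    if (length(sp$b) != nrow(sp$A))
      out <- c(out, sprintf("%s: %d bound specs for %d rows of A", sp$id,
                            length(sp$b), nrow(sp$A)))
    if (nrow(sp$T) != n_C)
      out <- c(out, sprintf("%s: T has %d rows, expected n_C = %d", sp$id,
                            nrow(sp$T), n_C))
    if (ncol(sp$T) != n_nu)
      out <- c(out, sprintf("%s: T has %d columns, expected %d", sp$id,
                            ncol(sp$T), n_nu))
    if (sp$growth_index < 1L || sp$growth_index > n_nu)
      out <- c(out, sprintf("%s: growth_index %d outside [1, %d]", sp$id,
                            sp$growth_index, n_nu))
    for (k in seq_along(sp$b)) {
      for (p in sp$b[[k]]$pieces) {
        if (length(p$gradient) != n_C)
          out <- c(out, sprintf(
            "%s: bound %d gradient length %d, expected n_C = %d", sp$id,
            k, length(p$gradient), n_C))
      }
      if (!(k %in% sp$uptake_rows) && !is_constant_bound(sp$b[[k]]))
        out <- c(out, sprintf(
          "%s: non-constant bound on row %d not flagged as uptake", sp$id, k))
    }
  }
  out
}

#' Evaluate piecewise-linear bounds at a concentration vector
#'
#' @param b list of [bound_spec()] objects.
#' @param C non-negative concentration vector.
#' @return numeric vector, element j = min over pieces of
#'   `intercept + gradient %*% C`.
#' @export
evaluate_bounds <- function(b, C) {
  vapply(b, function(spec) {
    vals <- vapply(spec$pieces, function(p) {
      if (length(p$gradient) != length(C))
        stop("bound gradient length does not match C")
      p$intercept + sum(p$gradient * C)
    }, 0)
    min(vals)
  }, 0)
}

# Gradient (Jacobian) of the bound vector: the gradient of the piece
# attaining the minimum. `choice` optionally fixes the piece per bound.
bound_gradient <- function(b, C, choice = NULL) {
  n_C <- length(C)
  G <- matrix(0, length(b), n_C)
  for (j in seq_along(b)) {
    spec <- b[[j]]
    if (!is.null(choice) && !is.na(choice[j])) {
      p <- spec$pieces[[choice[j]]]
    } else {
      vals <- vapply(spec$pieces, function(p) p$intercept + sum(p$gradient * C), 0)
      p <- spec$pieces[[which.min(vals)]]
    }
    G[j, ] <- p$gradient
  }
  G
}

#' Per-species net exchange fluxes, secretion-positive
#'
#' Reports, for each species and extracellular compound, the net exchange
#' scaled by that species' abundance: `-(T_i nu_i) * X_i` (or `x_i` in
#' batch modes). Positive entries are secretion, negative uptake. For a
#' chemostat solution the rows sum (with `D (C_in - C)`) to the
#' stationarity residual of each compound.
#'
#' @param model a [community_model()].
#' @param sol a [steady_state_solution()] carrying an abundance vector.
#' @return matrix (species x compounds) with dimnames.
#' @export
net_exchange <- function(model, sol) {
  ab <- if (!is.null(sol$X)) sol$X else sol$x
  if (is.null(ab)) stop("solution carries no abundance vector")
  n_C <- length(model$extracellular_ids)
  out <- matrix(0, length(model$species), n_C,
                dimnames = list(vapply(model$species, `[[`, "", "id"),
                                model$extracellular_ids))
  for (i in seq_along(model$species)) {
    sp <- model$species[[i]]
    out[i, ] <- -as.vector(sp$T %*% sol$nu[[i]]) * ab[i]
  }
  out
}
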
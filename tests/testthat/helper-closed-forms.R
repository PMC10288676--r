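# Closed-form reference values, derived independently of the solvers.

# Crossfeeding community under the rational-agent chemostat at inflow
# (S, 0, 0): without crossfeeding each species needs three units of S
# per unit growth (two for the expensive compound, one for the cheap
# one), so growth at rate D pins C_S at 3 D (uptake bound tight) and
# the substrate balance D (C_in - C_S) = 3 D * sum(X) gives the total
# abundance. The individual split is free: the steady states form the
# segment X1 + X2 = (C_in - 3 D) / 3.
pd_ca_closed_form <- function(D = 0.5, C_in_S = 10) {
  list(C_S = 3 * D, X_tot = (C_in_S - 3 * D) / 3)
}

# exact per-species KKT multipliers of the inner growth LP at
# C = (3D, 0, 0): uptake bounds tight, conversions and growth interior
pd_ca_multipliers <- function() {
  list(l1 = c(1 / 3, 2 / 3, 1 / 3, 0, 0, 0, 0,
              1 / 3, 1 / 3, 2 / 3, 0, 0, 0, 0),
       l2 = c(-1 / 3, -2 / 3, -1 / 3, -1 / 3, -1 / 3, -2 / 3))
}

# Two-nutrient coexistence fixture at D = 1, uptake caps 2 C: the
# growth demands (2,1) / (1,2) give, per inflow mixture (cA, cB):
#   single strain 1: X = min((cA - 1) / 2, cB - 1/2), when positive
#   coexistence:      X1 = (2 (cA-1) - (cB-1)) / 3,
#                     X2 = (2 (cB-1) - (cA-1)) / 3, both positive
coexist_closed_form <- function(cA, cB) {
  ss1 <- max(0, min((cA - 1) / 2, cB - 0.5))
  ss2 <- max(0, min((cB - 1) / 2, cA - 0.5))
  X1 <- (2 * (cA - 1) - (cB - 1)) / 3
  X2 <- (2 * (cB - 1) - (cA - 1)) / 3
  list(ss1 = ss1, ss2 = ss2,
       coex = if (X1 > 1e-9 && X2 > 1e-9) c(X1, X2))
}

abundance_matrix <- function(sols) {
  do.call(rbind, lapply(sols, function(s) if (!is.null(s$X)) s$X else s$x))
}

# set comparison up to tolerance on concatenated abundance/concentration
expect_same_solution_set <- function(a, b, tol = 1e-6) {
  key <- function(s) c(if (!is.null(s$X)) s$X else s$x,
                       if (!is.null(s$C)) s$C else s$mu_star)
  ka <- lapply(a, key); kb <- lapply(b, key)
  expect_equal(length(ka), length(kb))
  for (k in ka) {
    d <- vapply(kb, function(q) max(abs(q - k)), 0)
    expect_lt(min(d), tol)
  }
}

table2_pd <- list(
  CA = list(C = c(S = 1.5, A = 0, B = 0), X = c(1.42, 1.42),
            nu1 = c(t_S = 1.5, t_A = 0, t_B = 0, r_A = 0.5, r_B = 0.5,
                    mu = 0.5)),
  CC = list(C = c(S = 1.13, A = 0.5, B = 0.5), X = c(1.97, 1.97),
            nu1 = c(t_S = 1.13, t_A = 0.5, t_B = -0.627, r_A = 0,
                    r_B = 1.13, mu = 0.5)),
  BC = list(x = c(0.5, 0.5), mu_star = 5,
            nu1 = c(t_S = 10, t_A = 5, t_B = -5, r_A = 0, r_B = 10,
                    mu = 5)),
  CC12 = list(C = c(S = 3.6, A = 0, B = 0), X = c(1.07, 1.07),
              nu1 = c(t_S = 3.6, t_A = 0, t_B = 0, r_A = 1.2, r_B = 1.2,
                      mu = 1.2))
)

pd_envs <- function() list(
  CA = environment_spec("CA", D = 0.5, C_in = c(10, 0, 0)),
  CC = environment_spec("CC", D = 0.5, C_in = c(10, 0, 0)),
  CC12 = environment_spec("CC", D = 1.2, C_in = c(10, 0, 0)),
  BC = environment_spec("BC", u = c(10, 0, 0))
)
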
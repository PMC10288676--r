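# Abundance-grid MILP stage.

test_that("the big-M constant follows the documented policy", {
  m <- pd_network()
  expect_equal(choose_omega(m, environment_spec("CA", D = 0.5,
                                                C_in = c(10, 0, 0))), 100)
  # floor of 10 when nothing sets a scale
  m0 <- coexistence_network()
  expect_equal(choose_omega(m0, environment_spec("CA", D = 0.5,
                                                 C_in = c(0, 0))), 10)
  expect_error(choose_omega(m, environment_spec("BC", u = c(1, 0, 0))),
               "chemostat")
})

test_that("linearised complementarity emits the four big-M rows per pair", {
  m <- pd_network()
  sys <- assemble_system(m, environment_spec("CA", D = 0.5,
                                             C_in = c(10, 0, 0)))
  lin <- linearize_complementarity(sys, 100)
  expect_equal(lin$n_pairs, 14) # binaries = |lambda1|
  expect_equal(nrow(lin$A_ub), 4 * 14)
  nnu <- sum(sys$nnu); n_C <- sys$n_C
  o_l <- lin$offsets$lambda1; o_d <- lin$offsets$delta
  # Delta_j = 1 forces the constraint active: lambda free in [0, Omega],
  # q pinned at 0; Delta_j = 0 forces lambda = 0 with q free in [-Omega, 0]
  for (j in c(1L, 5L)) {
    rows <- lin$A_ub[4L * (j - 1L) + 1:4, , drop = FALSE]
    rhs <- lin$b_ub[4L * (j - 1L) + 1:4]
    probe <- function(lambda, qslack, delta) {
      v <- numeric(ncol(rows))
      # choose nu so that q_j = qslack with C = 0 (row j of A)
      arow <- sys$Ablk[j, ]
      k <- which(arow != 0)[1]
      v[k] <- qslack / arow[k]
      v[o_l + j] <- lambda
      v[o_d + j] <- delta
      all(rows %*% v <= rhs + 1e-9)
    }
    expect_true(probe(lambda = 50, qslack = 0, delta = 1))
    expect_false(probe(lambda = 150, qslack = 0, delta = 1)) # above Omega
    expect_false(probe(lambda = 50, qslack = -1, delta = 1)) # q must be 0
    expect_true(probe(lambda = 0, qslack = -1, delta = 0))
    expect_false(probe(lambda = 1, qslack = -1, delta = 0)) # lambda = 0
    expect_false(probe(lambda = 0, qslack = -200, delta = 0)) # below -Omega
  }
  expect_error(
    linearize_complementarity(
      assemble_system(pd_network(kinetic_bounds = FALSE),
                      environment_spec("BC", u = c(10, 0, 0))), 100),
    "chemostat")
})

test_that("minimal slack certifies steady states on and off the grid", {
  m <- pd_network()
  sys <- assemble_system(m, environment_spec("CA", D = 0.5,
                                             C_in = c(10, 0, 0)))
  om <- choose_omega(m, environment_spec("CA", D = 0.5, C_in = c(10, 0, 0)))
  cf <- pd_ca_closed_form()

  r <- solve_at_point(sys, om, rep(cf$X_tot / 2, 2))
  expect_equal(r$status, "optimal")
  expect_lt(r$slack, 1e-6)
  expect_lt(r$candidate$residual_max, 1e-6)
  # binary semantics hold exactly at the optimum
  lam <- r$candidate$lambda1
  qA <- as.vector(sys$Ablk %*% unlist(r$candidate$nu)) -
    evaluate_bounds(sys$bounds, r$candidate$C)
  expect_lt(max(abs(lam * qA)), 1e-7)

  expect_lt(solve_at_point(sys, om, c(0, 0))$slack, 1e-9)
  r5 <- solve_at_point(sys, om, c(5, 5))
  expect_gt(r5$slack, 0.1) # no steady state supports this biomass
})

test_that("grid maps are complete, ordered, and hit oracle abundances", {
  m <- coexistence_network()
  env <- environment_spec("CA", D = 1, C_in = c(5, 5))
  sys <- assemble_system(m, env)
  om <- choose_omega(m, env)
  g <- grid_spec(c(0, 0), c(2, 2), points = 3)
  res <- map_grid(sys, om, g)
  expect_length(res, 9) # points^n_X
  pts <- do.call(rbind, lapply(res, `[[`, "point"))
  # row-major: first species varies slowest
  expect_equal(pts[, 1], rep(c(0, 1, 2), each = 3))
  expect_equal(pts[, 2], rep(c(0, 1, 2), times = 3))
  expect_true(all(vapply(res, `[[`, 0, "slack") >= 0))
  # the grid contains the trivial and both single-strain states
  expect_lt(res[[1]]$slack, 1e-9) # (0, 0)
  # oracle abundances used as grid points give (near-)zero slack
  sols <- enumerate_solutions(m, env, n_starts = 2)
  for (s in sols) {
    r <- solve_at_point(sys, om, unname(s$X))
    expect_lt(r$slack, 1e-6)
    expect_lt(r$candidate$residual_max, 1e-6)
  }

  single <- map_grid(sys, om, grid_spec(c(0, 0), c(0, 0), points = 1))
  expect_length(single, 1)
  expect_lt(single[[1]]$slack, 1e-9)
})
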
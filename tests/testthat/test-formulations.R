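# Algebraic system assembly, residual evaluation, inner-LP certification.

test_that("assembled systems have the documented variable structure", {
  m <- pd_network()
  sys <- assemble_system(m, environment_spec("CA", D = 0.5,
                                             C_in = c(10, 0, 0)))
  expect_equal(sum(sys$nnu), 12) # 6 reactions x 2 species
  expect_length(sys$layout$C, 3)
  expect_length(sys$layout$X, 2)
  expect_length(sys$layout$l1, 14) # 7 capacity rows per species
  # one independent KKT block per species
  expect_equal(sum(grepl("^stat\\.sp1", sys$eq_names)), 6)
  expect_equal(sum(grepl("^stat\\.sp2", sys$eq_names)), 6)

  sysba <- assemble_system(pd_network(kinetic_bounds = FALSE),
                           environment_spec("BA", u = c(10, 0, 0)))
  expect_null(sysba$layout$C) # no concentration representation in batch
  expect_false(is.null(sysba$layout$x))
  expect_false(is.null(sysba$layout$mu_star))

  syscc <- assemble_system(m, environment_spec("CC", D = 0.5,
                                               C_in = c(10, 0, 0)))
  expect_length(syscc$layout$l1, 17) # + one multiplier per C >= 0
  expect_true(any(grepl("^statC", syscc$eq_names)))
})

test_that("environment invariants are enforced", {
  expect_error(environment_spec("CA", D = 0.5, C_in = c(1, 0),
                                u = c(1, 0)), "no u")
  expect_error(environment_spec("BC", D = 1, u = c(1, 0)), "neither D")
  expect_error(environment_spec("CA", D = 0.5, C_in = c(1, 0),
                                objective = "sum_growth"), "no objective")
  expect_error(environment_spec("CA", D = -1, C_in = c(1, 0)), "positive")
  # batch modes refuse concentration-dependent capacity bounds
  expect_error(assemble_system(pd_network(),
                               environment_spec("BC", u = c(10, 0, 0))),
               "constant bounds")
})

test_that("printed crossfeeding-free state satisfies the agent system", {
  m <- pd_network()
  sys <- assemble_system(m, environment_spec("CA", D = 0.5,
                                             C_in = c(10, 0, 0)))
  mult <- pd_ca_multipliers()
  # rounded printed values: residual only reflects the rounding
  ca <- table2_pd$CA
  sol <- steady_state_solution(nu = list(sp1 = ca$nu1, sp2 = ca$nu1),
                               C = ca$C, X = ca$X,
                               lambda1 = mult$l1, lambda2 = mult$l2)
  expect_lt(residual(sys, sol)$residual_max, 0.02)

  # exact closed-form values: residual at machine precision
  cf <- pd_ca_closed_form()
  nu <- c(1.5, 0, 0, 0.5, 0.5, 0.5)
  exact <- steady_state_solution(nu = list(sp1 = nu, sp2 = nu),
                                 C = c(cf$C_S, 0, 0),
                                 X = rep(cf$X_tot / 2, 2),
                                 lambda1 = mult$l1, lambda2 = mult$l2)
  expect_lt(residual(sys, exact)$residual_max, 1e-12)

  # doubling one abundance breaks the substrate balance by 1.5 * X
  pert <- exact
  pert$X <- c(2, 1) * exact$X
  rep <- residual(sys, pert)
  expect_equal(abs(rep$breakdown[["massbal.S_e"]]), 1.5 * cf$X_tot / 2,
               tolerance = 1e-9)
})

test_that("washout requires optimal fluxes, not zero fluxes", {
  m <- pd_network()
  sys <- assemble_system(m, environment_spec("CA", D = 0.5,
                                             C_in = c(10, 0, 0)))
  mult <- pd_ca_multipliers()
  # true washout: inner argmax at C = C_in with its multipliers
  nu0 <- c(10, 0, 0, 10 / 3, 10 / 3, 10 / 3)
  wash <- steady_state_solution(nu = list(sp1 = nu0, sp2 = nu0),
                                C = c(10, 0, 0), X = c(0, 0),
                                lambda1 = mult$l1, lambda2 = mult$l2)
  expect_lt(residual(sys, wash)$residual_max, 1e-12)
  # an all-zero candidate violates the KKT stationarity rows
  zero <- steady_state_solution(nu = list(sp1 = rep(0, 6),
                                          sp2 = rep(0, 6)),
                                C = c(10, 0, 0), X = c(0, 0),
                                lambda1 = rep(0, 14), lambda2 = rep(0, 6))
  expect_gt(residual(sys, zero)$residual_max, 0.5)
})

test_that("inner-LP certification is independent of the multipliers", {
  m <- pd_network()
  envca <- environment_spec("CA", D = 0.5, C_in = c(10, 0, 0))
  cf <- pd_ca_closed_form()
  nu <- c(1.5, 0, 0, 0.5, 0.5, 0.5)
  cand <- steady_state_solution(nu = list(sp1 = nu, sp2 = nu),
                                C = c(cf$C_S, 0, 0),
                                X = rep(cf$X_tot / 2, 2))
  expect_lt(verify_inner_optimality(m, envca, cand), 1e-9)

  # a feasible but suboptimal growth rate shows up as the exact gap
  sub <- cand
  sub$nu$sp1 <- c(1.2, 0, 0, 0.4, 0.4, 0.4)
  expect_equal(verify_inner_optimality(m, envca, sub), 0.1,
               tolerance = 1e-7)

  # community certificate at the printed crossfeeding state
  envcc <- environment_spec("CC", D = 0.5, C_in = c(10, 0, 0))
  sols <- enumerate_solutions(m, envcc, n_starts = 2)
  ab <- abundance_matrix(sols)
  sym <- sols[[which.min(abs(ab[, 1] - 1.97) + abs(ab[, 2] - 1.97))]]
  expect_lt(verify_inner_optimality(m, envcc, sym), 1e-6)
  # the certified optimum equals D * total biomass
  val <- sum(vapply(seq_along(sym$nu), function(i)
    sym$nu[[i]][["mu"]] * sym$X[i], 0))
  expect_equal(val, 0.5 * sum(sym$X), tolerance = 1e-8)
})

test_that("without concentration feedback only the trivial state survives", {
  m <- coexistence_network(bound_type = "constant")
  # generic dilution rate away from the constant maximal growth rate
  sols <- enumerate_solutions(m, environment_spec("CA", D = 0.7,
                                                  C_in = c(5, 5)))
  expect_equal(length(sols), 1L)
  expect_equal(unname(sols[[1]]$X), c(0, 0))
})
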
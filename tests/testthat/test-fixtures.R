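# Built-in example communities and sweeps.

test_that("crossfeeding network stoichiometry matches its description", {
  m <- pd_network()
  sp1 <- m$species[[1]]
  # growth consumes one unit each of the two intracellular products
  expect_equal(sp1$S[, "mu"], c(S_c = 0, A_c = -1, B_c = -1))
  # species 1 produces A expensively (two units of substrate per unit)
  expect_equal(sp1$S[, "r_A"], c(S_c = -2, A_c = 1, B_c = 0))
  expect_equal(sp1$S[, "r_B"], c(S_c = -1, A_c = 0, B_c = 1))
  # the relabelling (A<->B, species 1<->2) maps the model onto itself
  sp2 <- m$species[[2]]
  perm_r <- c("t_S", "t_B", "t_A", "r_B", "r_A", "mu")
  perm_m <- c("S_c", "B_c", "A_c")
  expect_equal(unname(sp2$S[perm_m, perm_r]), unname(sp1$S))
  expect_equal(length(validate_community(m)), 0)
  expect_equal(length(validate_community(pd_network(kinetic_bounds = FALSE))), 0)
})

test_that("coexistence network demands are asymmetric and uptake-only", {
  m <- coexistence_network()
  expect_equal(m$species[[1]]$S[, "mu"], c(A_c = -2, B_c = -1))
  expect_equal(m$species[[2]]$S[, "mu"], c(A_c = -1, B_c = -2))
  # swapping compounds and species yields an identical model
  expect_equal(unname(m$species[[2]]$S[2:1, c(2, 1, 3)]),
               unname(m$species[[1]]$S))
  expect_error(coexistence_network(a1 = 1, b1 = 1), "a1 > b1")
  expect_error(coexistence_network(a2 = 2, b2 = 1), "b2 > a2")
})

test_that("random communities are reproducible and admit the trivial state", {
  m1 <- random_community(seed = 1)
  m2 <- random_community(seed = 1)
  expect_equal(m1, m2)
  m3 <- random_community(seed = 2)
  expect_false(isTRUE(all.equal(m1$species[[1]]$S, m3$species[[1]]$S)))
  expect_length(validate_community(m1), 0)
  # the washout candidate satisfies the assembled system
  env <- environment_spec("CA", D = 0.4, C_in = c(3, 2))
  sols <- enumerate_solutions(m1, env, n_starts = 2)
  expect_true(any(vapply(sols, function(s) max(s$X) < 1e-9, TRUE)))
})

test_that("environment sweeps interpolate linearly and copy other fields", {
  base <- environment_spec("CA", D = 1, C_in = c(0, 10))
  envs <- sweep_environments(base, c(0, 10), c(10, 0), 3)
  expect_equal(envs[[2]]$C_in, c(5, 5))
  expect_equal(envs[[1]]$C_in, c(0, 10))
  expect_equal(envs[[3]]$C_in, c(10, 0))
  expect_true(all(vapply(envs, function(e) e$D, 0) == 1))
  bb <- environment_spec("BC", u = c(0, 1))
  ee <- sweep_environments(bb, c(0, 1), c(1, 0), 5)
  expect_equal(ee[[3]]$u, c(0.5, 0.5))
  expect_error(sweep_environments(base, c(0, 1, 2), c(1, 0), 3), "length")
})

test_that("crossfeeding appears under the community chemostat only at low flow", {
  m <- pd_network()
  # rational agents never crossfeed
  sa <- enumerate_solutions(m, environment_spec("CA", D = 0.5,
                                                C_in = c(10, 0, 0)),
                            n_starts = 2)
  for (s in sa) {
    expect_lt(abs(s$nu$sp1[["t_A"]]), 1e-8)
    expect_lt(abs(s$nu$sp1[["t_B"]]), 1e-8)
  }
  # the community model at high flow abandons crossfeeding
  s12 <- enumerate_solutions(m, environment_spec("CC", D = 1.2,
                                                 C_in = c(10, 0, 0)),
                             n_starts = 2)
  ab <- abundance_matrix(s12)
  coex <- which(ab[, 1] > 1e-6 & ab[, 2] > 1e-6)
  expect_gt(length(coex), 0)
  for (k in coex) {
    expect_lt(abs(s12[[k]]$nu$sp1[["t_A"]]), 1e-8)
    expect_lt(abs(s12[[k]]$nu$sp1[["t_B"]]), 1e-8)
  }
})
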
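# Active-set enumeration oracle.

test_that("pattern enumeration covers the full branch space", {
  m <- pd_network()
  sys <- assemble_system(m, environment_spec("CA", D = 0.5,
                                             C_in = c(10, 0, 0)))
  it <- enumerate_patterns(sys)
  expect_equal(it$count, 2^(14 + 2))
  expect_equal(it$n_delta, 14)
  p1 <- it$get(1)
  expect_s3_class(p1, "complementarity_pattern")
  expect_true(all(p1$delta == 0) && all(p1$support == 0))
  plast <- it$get(it$count)
  expect_true(all(plast$delta == 1) && all(plast$support == 1))
  expect_error(enumerate_patterns(sys, max_patterns = 1), "budget")

  # a capacity-free single species leaves only the support choice
  sp <- species_network("solo", "M", c("t", "mu"),
                        S = rbind(c(1, -1)),
                        A = matrix(0, 0, 2), b = list(),
                        T = rbind(c(1, 0)), growth_index = 2L)
  solo <- community_model(list(sp), "E")
  syss <- assemble_system(solo, environment_spec("CA", D = 1, C_in = 2))
  expect_equal(enumerate_patterns(syss)$count, 2)
})

test_that("individual branches solve to their closed-form roots", {
  m <- pd_network()
  sys <- assemble_system(m, environment_spec("CA", D = 0.5,
                                             C_in = c(10, 0, 0)))
  cf <- pd_ca_closed_form()
  # both species at D-growth, all three uptake bounds tight
  both <- complementarity_pattern(
    delta = c(1, 1, 1, 0, 0, 0, 0, 1, 1, 1, 0, 0, 0, 0),
    support = c(1, 1))
  roots <- solve_pattern(sys, both, n_starts = 6, seed = 1)
  expect_gt(length(roots), 0)
  for (r in roots) {
    expect_equal(unname(r$C[1]), cf$C_S, tolerance = 1e-9)
    expect_equal(sum(r$X), cf$X_tot, tolerance = 1e-8)
    expect_lt(r$residual_max, 1e-8)
  }
  # species 2 absent but still flux-optimal: its uptake bounds are
  # tight at the shared concentrations, so its pairs are active too
  single <- complementarity_pattern(
    delta = c(1, 1, 1, 0, 0, 0, 0, 1, 1, 1, 0, 0, 0, 0),
    support = c(1, 0))
  roots <- solve_pattern(sys, single, n_starts = 4, seed = 1)
  expect_gt(length(roots), 0)
  expect_equal(unname(roots[[1]]$X), c(cf$X_tot, 0), tolerance = 1e-8)
  # a contradictory branch is simply empty
  bad <- complementarity_pattern(
    delta = c(0, 0, 0, 1, 1, 1, 1, rep(0, 7)), # D-growth with all
    support = c(1, 0))                         # conversions shut off
  expect_length(solve_pattern(sys, bad, n_starts = 3, seed = 1), 0)
})

test_that("agent enumeration recovers the crossfeeding-free solution set", {
  m <- pd_network()
  sols <- enumerate_solutions(m, environment_spec("CA", D = 0.5,
                                                  C_in = c(10, 0, 0)),
                              n_starts = 4)
  cf <- pd_ca_closed_form()
  ab <- abundance_matrix(sols)
  # washout present
  expect_true(any(rowSums(ab) < 1e-9))
  # both single-strain states present
  expect_true(any(abs(ab[, 1] - cf$X_tot) < 1e-6 & ab[, 2] < 1e-9))
  expect_true(any(abs(ab[, 2] - cf$X_tot) < 1e-6 & ab[, 1] < 1e-9))
  nontrivial <- ab[rowSums(ab) > 1e-9, , drop = FALSE]
  # every non-trivial state sits on the closed-form segment, and no
  # accepted state crossfeeds
  expect_true(all(abs(rowSums(nontrivial) - cf$X_tot) < 1e-6))
  for (s in sols) {
    expect_lt(abs(s$nu$sp1[["t_A"]]), 1e-8)
    expect_lt(abs(s$nu$sp1[["t_B"]]), 1e-8)
  }
  # the symmetric representative is reported
  expect_true(any(abs(ab[, 1] - ab[, 2]) < 1e-6 & rowSums(ab) > 1))
})

test_that("solution sets inherit the species-exchange symmetry", {
  m <- pd_network()
  # isolated community states: the mirrored state is in the set
  sols <- enumerate_solutions(m, environment_spec("CC", D = 0.5,
                                                  C_in = c(10, 0, 0)),
                              n_starts = 2, seed = 3)
  ab <- abundance_matrix(sols)
  for (r in seq_len(nrow(ab))) {
    d <- apply(ab, 1L, function(q) max(abs(q - rev(ab[r, ]))))
    expect_lt(min(d), 1e-6)
  }
  # the agent continuum is mirror-invariant: swapping species and
  # compounds maps every representative onto another steady state
  sa <- enumerate_solutions(m, environment_spec("CA", D = 0.5,
                                                C_in = c(10, 0, 0)),
                            n_starts = 2, seed = 3)
  sys <- assemble_system(m, environment_spec("CA", D = 0.5,
                                             C_in = c(10, 0, 0)))
  perm <- c("t_S", "t_B", "t_A", "r_B", "r_A", "mu")
  for (s in sa) {
    sw <- s
    sw$nu <- list(sp1 = stats::setNames(s$nu$sp2[perm], names(s$nu$sp2)),
                  sp2 = stats::setNames(s$nu$sp1[perm], names(s$nu$sp1)))
    sw$C <- stats::setNames(s$C[c(1, 3, 2)], names(s$C))
    sw$X <- stats::setNames(rev(s$X), names(s$X))
    l1m <- matrix(s$lambda1, ncol = 2)[c(1, 3, 2, 4, 6, 5, 7), 2:1]
    sw$lambda1 <- as.vector(l1m)
    l2m <- matrix(s$lambda2, ncol = 2)[c(1, 3, 2), 2:1]
    sw$lambda2 <- as.vector(l2m)
    expect_lt(residual(sys, sw)$residual_max, 1e-8)
  }
})

test_that("high dilution washes the community out", {
  m <- pd_network()
  sols <- enumerate_solutions(m, environment_spec("CA", D = 10,
                                                  C_in = c(10, 0, 0)))
  expect_equal(length(sols), 1L)
  expect_equal(max(sols[[1]]$X), 0)
})

test_that("accepted solutions satisfy the steady-state invariants", {
  m <- synthetic_syntrophic_pair()
  env <- synthetic_syntrophic_env("CA")
  sols <- enumerate_solutions(m, env, n_starts = 3)
  expect_gt(length(sols), 3)
  for (s in sols) {
    expect_lt(s$residual_max, 1e-8)
    expect_lt(verify_inner_optimality(m, env, s), 1e-6)
    for (i in seq_len(2)) {
      if (s$X[i] > 1e-9) {
        expect_lt(abs(s$nu[[i]][["mu"]] - env$D), 1e-8)
      }
    }
  }
})

test_that("batch enumeration enforces the community steady state", {
  m <- pd_network(kinetic_bounds = FALSE)
  sols <- enumerate_solutions(m, environment_spec("BC", u = c(10, 0, 0)),
                              n_starts = 3)
  for (s in sols) {
    expect_lt(abs(sum(s$x) - 1), 1e-8)
    for (i in 1:2) if (s$x[i] > 1e-9) {
      expect_lt(abs(s$nu[[i]][["mu"]] - s$mu_star), 1e-8)
    }
  }
  ab <- abundance_matrix(sols)
  expect_true(any(abs(ab[, 1] - 0.5) < 1e-6 & abs(ab[, 2] - 0.5) < 1e-6))
})
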
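# Levenberg-Marquardt refinement, acceptance filtering, deduplication.

test_that("refinement converges from printed-precision starts", {
  m <- pd_network()
  env <- environment_spec("CC", D = 0.5, C_in = c(10, 0, 0))
  sys <- assemble_system(m, env)
  t2 <- table2_pd$CC
  nu2 <- t2$nu1[c("t_S", "t_B", "t_A", "r_B", "r_A", "mu")]
  names(nu2) <- names(t2$nu1)
  start <- steady_state_solution(
    nu = list(sp1 = t2$nu1, sp2 = nu2),
    C = t2$C[c("S", "A", "B")], X = t2$X,
    lambda1 = rep(0, 17), lambda2 = rep(0, 9))
  out <- refine(sys, start)
  expect_lt(out$residual_max, 1e-8)
  expect_lt(max(abs(out$X - c(1.97, 1.97))), 0.01)
})

test_that("refinement is monotone and leaves exact solutions in place", {
  m <- pd_network()
  env <- environment_spec("CA", D = 0.5, C_in = c(10, 0, 0))
  sys <- assemble_system(m, env)
  exact <- enumerate_solutions(m, env, n_starts = 2)[[2]]
  out <- refine(sys, exact)
  expect_lt(max(abs(solution_to_z(sys, out) - solution_to_z(sys, exact))),
            1e-7)
  set.seed(5)
  for (k in 1:5) {
    z <- runif(sys$n_z, -1, 3)
    start <- z_to_solution(sys, z)
    ref <- refine(sys, start)
    expect_lte(ref$residual_ssq, start$residual_ssq + 1e-12)
  }
  bad <- z_to_solution(sys, rep(NaN, sys$n_z))
  expect_error(refine(sys, bad), "non-finite")
})

test_that("acceptance keeps exactly the certified near-zero residuals", {
  m <- pd_network()
  env <- environment_spec("CA", D = 0.5, C_in = c(10, 0, 0))
  sys <- assemble_system(m, env)
  good <- enumerate_solutions(m, env, n_starts = 2)
  off <- good[[2]]
  off$X <- off$X + 0.01
  off <- z_to_solution(sys, solution_to_z(sys, off))
  kept <- accept_solutions(c(good, list(off)), m, env)
  expect_length(kept, length(good))
})

test_that("deduplication merges numerically identical states only", {
  m <- pd_network()
  env <- environment_spec("CA", D = 0.5, C_in = c(10, 0, 0))
  sols <- enumerate_solutions(m, env, n_starts = 2)
  s <- sols[[1]]
  s_jit <- s
  s_jit$X <- s$X + 1e-8
  expect_length(dedupe_solutions(list(s, s, s_jit)), 1)
  far <- s
  far$X <- s$X + 0.5
  expect_length(dedupe_solutions(list(s, far)), 2)
})

test_that("grid + refinement + acceptance reproduces the oracle set", {
  m <- coexistence_network()
  env <- environment_spec("CA", D = 1, C_in = c(5, 5))
  sys <- assemble_system(m, env)
  om <- choose_omega(m, env)
  res <- map_grid(sys, om, grid_spec(c(0, 0), c(2, 2), points = 3))
  cands <- Filter(Negate(is.null), lapply(res, `[[`, "candidate"))
  refined <- lapply(cands, function(c0) refine(sys, c0))
  kept <- dedupe_solutions(accept_solutions(refined, m, env))
  oracle <- enumerate_solutions(m, env, n_starts = 2)
  # every refined accepted state matches an oracle state
  oab <- abundance_matrix(oracle)
  for (s in kept) {
    d <- apply(oab, 1L, function(q) max(abs(q - s$X)))
    expect_lt(min(d), 1e-6)
  }
  # the pipeline recovers the complete oracle set here
  kab <- abundance_matrix(kept)
  for (r in seq_len(nrow(oab))) {
    d <- apply(kab, 1L, function(q) max(abs(q - oab[r, ])))
    expect_lt(min(d), 1e-6)
  }
})

test_that("crossfed-limited growth yields a band of coexistence states", {
  m <- synthetic_syntrophic_pair()
  env <- synthetic_syntrophic_env("CA")
  sols <- enumerate_solutions(m, env, n_starts = 3)
  ab <- abundance_matrix(sols)
  coex <- ab[ab[, 1] > 1e-6 & ab[, 2] > 1e-6, , drop = FALSE]
  # distinct abundance vectors, not one isolated point
  coex_u <- unique(round(coex, 3))
  expect_gte(nrow(coex_u), 3)
})
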
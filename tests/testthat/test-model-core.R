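# Domain types, validation, bound evaluation, exchange reporting.

test_that("validate_community reports structural violations by name", {
  expect_length(validate_community(pd_network()), 0)

  m <- pd_network()
  m$species[[1]]$growth_index <- 7L # == n_nu + 1
  expect_match(validate_community(m), "growth_index", all = FALSE)

  m <- pd_network()
  m$species[[2]]$T <- m$species[[2]]$T[1:2, ] # wrong n_C
  expect_match(validate_community(m), "T has 2 rows", all = FALSE)

  m <- pd_network()
  m$species[[2]]$id <- "sp1"
  expect_match(validate_community(m), "duplicate", all = FALSE)

  # non-constant bound outside the declared uptake rows
  m <- pd_network()
  m$species[[1]]$uptake_rows <- 2:3
  expect_match(validate_community(m), "not flagged as uptake", all = FALSE)
})

test_that("evaluate_bounds takes the minimum over affine pieces", {
  b1 <- bound_spec(list(list(intercept = 0, gradient = c(1, 0, 0))))
  expect_equal(evaluate_bounds(list(b1), c(1.5, 0, 0)), 1.5)
  expect_equal(evaluate_bounds(list(constant_bound(2, 3)), c(9, 9, 9)), 2)
  b2 <- bound_spec(list(list(intercept = 0, gradient = 2),
                        list(intercept = 4, gradient = 0)))
  expect_equal(evaluate_bounds(list(b2), 1), 2)
  expect_equal(evaluate_bounds(list(b2), 5), 4)
  expect_error(evaluate_bounds(list(b1), c(1, 2)), "length")
})

test_that("piecewise bounds are concave in the concentrations", {
  set.seed(11)
  for (k in 1:20) {
    n_C <- sample(1:3, 1)
    pieces <- lapply(seq_len(sample(1:4, 1)), function(i)
      list(intercept = runif(1, 0, 3), gradient = runif(n_C, -1, 2)))
    b <- list(bound_spec(pieces))
    C1 <- runif(n_C, 0, 5); C2 <- runif(n_C, 0, 5); t <- runif(1)
    lhs <- evaluate_bounds(b, t * C1 + (1 - t) * C2)
    rhs <- t * evaluate_bounds(b, C1) + (1 - t) * evaluate_bounds(b, C2)
    expect_gte(lhs, rhs - 1e-12)
  }
})

test_that("net exchange is secretion-positive and abundance-scaled", {
  m <- pd_network()
  # printed crossfeeding state: species 1 takes up A, secretes B
  t2 <- table2_pd$CC
  sol <- steady_state_solution(
    nu = list(sp1 = t2$nu1,
              sp2 = t2$nu1[c("t_S", "t_B", "t_A", "r_B", "r_A", "mu")]),
    C = t2$C[c("S", "A", "B")], X = t2$X)
  names(sol$nu$sp2) <- names(t2$nu1)
  ex <- net_exchange(m, sol)
  expect_equal(ex["sp1", "B_e"], 0.627 * 1.97, tolerance = 1e-9)
  expect_equal(ex["sp1", "A_e"], -0.5 * 1.97, tolerance = 1e-9)
  expect_equal(ex["sp1", "S_e"], -1.13 * 1.97, tolerance = 1e-9)

  # direct substitution of the rational-agent state: pure S uptake
  ca <- table2_pd$CA
  solca <- steady_state_solution(nu = list(sp1 = ca$nu1, sp2 = ca$nu1),
                                 C = ca$C, X = c(1.42, 1.42))
  exca <- net_exchange(m, solca)
  expect_equal(exca["sp1", "S_e"], -1.5 * 1.42)

  zero <- steady_state_solution(nu = list(sp1 = ca$nu1 * 0,
                                          sp2 = ca$nu1 * 0),
                                C = ca$C, X = c(1, 1))
  expect_true(all(net_exchange(m, zero) == 0))
  expect_error(net_exchange(m, steady_state_solution(nu = list(0, 0))),
               "abundance")
})

test_that("exchange rows close the chemostat mass balance", {
  m <- pd_network()
  env <- environment_spec("CA", D = 0.5, C_in = c(10, 0, 0))
  sols <- enumerate_solutions(m, env, n_starts = 2)
  for (s in sols) {
    ex <- net_exchange(m, s)
    resid <- env$D * (env$C_in - s$C) + colSums(ex)
    expect_lt(max(abs(resid)), 3 * 1e-8)
  }
})

test_that("community models round-trip through JSON", {
  m <- coexistence_network()
  path <- tempfile(fileext = ".json")
  write_community_json(m, path)
  m2 <- read_community_json(path)
  expect_equal(length(validate_community(m2)), 0)
  for (i in 1:2) {
    expect_equal(m2$species[[i]]$S, m$species[[i]]$S)
    expect_equal(m2$species[[i]]$A, m$species[[i]]$A, ignore_attr = TRUE)
    expect_equal(m2$species[[i]]$T, m$species[[i]]$T)
    expect_equal(m2$species[[i]]$b, m$species[[i]]$b)
    expect_equal(m2$species[[i]]$growth_index, m$species[[i]]$growth_index)
  }
})
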
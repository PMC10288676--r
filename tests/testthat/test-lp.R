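# Linear and mixed-binary solver backends.

test_that("solve_lp handles equalities, free variables and bounds", {
  r <- commsteady:::solve_lp(c(2, 3), A_ub = rbind(c(1, 1), c(1, 3)),
                             b_ub = c(4, 6), lower = 0, maximize = TRUE)
  expect_equal(r$status, "optimal")
  expect_equal(r$value, 9)
  expect_equal(r$x, c(3, 1))

  # free variables on an equality: bounded only from below through x >= 0
  r <- commsteady:::solve_lp(c(1, 1), A_eq = rbind(c(1, -1)), b_eq = -2,
                             lower = 0)
  expect_equal(r$value, 2)

  # negative lower bound honoured
  r <- commsteady:::solve_lp(1, A_ub = rbind(1), b_ub = 10, lower = -3)
  expect_equal(r$value, -3)

  # two-sided bounds
  r <- commsteady:::solve_lp(c(1, 2), A_ub = rbind(c(1, 1)), b_ub = 2,
                             lower = c(0, -1), upper = c(1, 2),
                             maximize = TRUE)
  expect_equal(r$value, 4)

  expect_equal(commsteady:::solve_lp(c(1, 1),
                                     A_eq = rbind(c(1, -1)),
                                     b_eq = -2)$status, "unbounded")
  expect_equal(commsteady:::solve_lp(1, A_ub = rbind(1), b_ub = 1,
                                     A_eq = rbind(1), b_eq = 3,
                                     lower = 0)$status, "infeasible")
})

test_that("solve_lp optima agree with an independent simplex on random programs", {
  skip_if_not_installed("boot")
  set.seed(42)
  for (k in 1:40) {
    n <- sample(2:6, 1)
    mI <- sample(1:5, 1)
    A <- matrix(round(runif(mI * n, -2, 2), 2), mI, n)
    b <- round(runif(mI, 0.5, 4), 2)
    a <- round(runif(n, -2, 2), 2)
    ref <- tryCatch(boot::simplex(a = a, A1 = A, b1 = b, maxi = TRUE),
                    error = function(e) NULL)
    mine <- commsteady:::solve_lp(a, A_ub = A, b_ub = b, lower = 0,
                                  maximize = TRUE)
    if (!is.null(ref) && ref$solved == 1) {
      expect_equal(mine$status, "optimal")
      expect_equal(mine$value, unname(ref$value), tolerance = 1e-7)
    }
  }
})

test_that("returned optima are always primal feasible", {
  set.seed(7)
  for (k in 1:60) {
    n <- sample(2:8, 1)
    mI <- sample(0:5, 1); mE <- sample(0:3, 1)
    A <- if (mI) matrix(round(runif(mI * n, -2, 2), 2), mI) else NULL
    b <- if (mI) round(runif(mI, -1, 3), 2) else NULL
    E <- if (mE) matrix(round(runif(mE * n, -2, 2), 2), mE) else NULL
    be <- if (mE) round(runif(mE, -1, 1), 2) else NULL
    lo <- ifelse(runif(n) < 0.4, -Inf, round(runif(n, -2, 0), 2))
    up <- ifelse(runif(n) < 0.4, Inf, round(runif(n, 0.5, 2), 2))
    r <- commsteady:::solve_lp(round(runif(n, -1, 1), 2), A, b, E, be,
                               lo, up, maximize = k %% 2 == 0)
    if (r$status == "optimal") {
      v <- max(c(0, if (mE) abs(E %*% r$x - be), if (mI) A %*% r$x - b,
                 lo - r$x, r$x - up))
      expect_lt(v, 1e-6)
    }
    # the dedicated feasibility test agrees with the full solve
    expect_identical(
      commsteady:::lp_feasible(n, A, b, E, be, lo, up),
      r$status != "infeasible")
  }
})

test_that("branch-and-bound reaches the integer optimum", {
  # knapsack-style: max 5a+4b+3c, 2a+3b+c <= 5, binaries -> (1,1,0)
  r <- commsteady:::solve_milp(c(-5, -4, -3),
                               A_ub = rbind(c(2, 3, 1)), b_ub = 5,
                               lower = 0, upper = 1, binary = 1:3)
  expect_equal(r$status, "optimal")
  expect_equal(r$value, -9)
  expect_equal(round(r$x), c(1, 1, 0))

  # infeasible integer system
  r <- commsteady:::solve_milp(c(1), A_eq = rbind(1), b_eq = 0.5,
                               binary = 1L)
  expect_equal(r$status, "infeasible")

  # mixed continuous/binary
  r <- commsteady:::solve_milp(c(1, -2), A_ub = rbind(c(1, 1)), b_ub = 1.5,
                               lower = c(0, 0), upper = c(5, 1),
                               binary = 2L)
  expect_equal(r$value, -2)
})
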
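# Distances, the GREG closed form, the restricted quadratic program and the
# two calibration drivers, against closed forms, quadprog and grid oracles.

test_that("chi-square and raking distances evaluate their closed forms", {
  expect_equal(chi_square_distance(rep(2, 5), rep(2, 5)), 0)
  expect_equal(chi_square_distance(1:4, rep(1, 4)), 14)
  expect_equal(chi_square_distance(rep(20.16, 100), rep(20, 100)), 0.128)
  expect_error(chi_square_distance(1, 0), "strictly positive")

  expect_equal(mdi_distance(rep(3, 4), rep(3, 4)), 0)
  expect_equal(mdi_distance(exp(1), 1), 1)
  expect_equal(mdi_distance(0, 2), 2)  # limit convention w log w -> 0
  expect_error(mdi_distance(-1, 1), "nonnegative")
})

test_that("GREG closed form reproduces the worked and hand examples", {
  w <- greg_weights(matrix(1, 100, 1), rep(20, 100), 2016)
  expect_equal(w, rep(20.16, 100))
  expect_equal(greg_weights(matrix(c(1, 2), 2, 1), c(1, 1), 4), c(1.2, 1.4))
  # design-weight fixpoint and constraint satisfaction
  set.seed(31)
  X <- matrix(rnorm(40), 10, 4)
  d <- runif(10, 1, 3)
  expect_equal(greg_weights(X, d, as.vector(crossprod(X, d))), d)
  t_x <- as.vector(crossprod(X, d)) + rnorm(4)
  expect_lt(max(abs(crossprod(X, greg_weights(X, d, t_x)) - t_x)), 1e-8)
  # collinear benchmark columns are named in the failure
  expect_error(greg_weights(cbind(x1 = 1:4, x2 = 2 * (1:4)), rep(1, 4),
                            c(10, 20)), "collinear.*x2")
})

test_that("restricted solve at the worked example hits both branches", {
  # budget 16 with bounds [0,20]: d itself is feasible and optimal
  res <- solve_restricted(intro_example(u = 20), tae_budget = 16)
  expect_equal(res$w, rep(20, 100), tolerance = 1e-6)
  expect_equal(res$distance, 0, tolerance = 1e-6)
  # positivity-only with zero budget: the GREG point
  res2 <- solve_restricted(intro_example(), tae_budget = 0)
  expect_equal(res2$w, rep(20.16, 100), tolerance = 1e-7)
})

test_that("with inactive bounds and zero budget the QP equals GREG", {
  for (k in 1:10) {
    set.seed(900 + k)
    n <- sample(4:20, 1)
    p <- sample(1:3, 1)
    X <- matrix(rnorm(n * p), n, p)
    d <- runif(n, 0.5, 2)
    t_x <- as.vector(crossprod(X, d)) + rnorm(p, sd = 0.2)
    wg <- greg_weights(X, d, t_x)
    pr <- as_problem(X, d, t_x, l = -Inf, u = Inf)
    res <- solve_restricted(pr, 0)
    expect_lt(max(abs(res$w - wg)) / max(1, max(abs(wg))), 1e-6)
  }
})

test_that("QP optimum is a global lower bound over the feasible grid", {
  for (k in 1:8) {
    prm <- random_tiny_problem(n = 3, p = 2, seed = 1100 + k)
    pr <- as_problem(prm$X, prm$d, prm$t_x, l = prm$l, u = prm$u)
    fe <- min_tae(pr)
    budget <- fe$tae_star * (1 + 1e-9) + 1e-9
    res <- solve_restricted(pr, budget)
    W <- grid_points(prm$l, prm$u, 21L)
    tae_g <- as.vector(abs(W %*% prm$X -
                             matrix(prm$t_x, nrow(W), 2, byrow = TRUE)) %*%
                         prm$r)
    feas <- W[tae_g <= budget + 1e-9, , drop = FALSE]
    if (!nrow(feas)) next
    gobj <- min(colSums((t(feas) - prm$d)^2 / prm$d))
    expect_lte(res$distance, gobj + 1e-6 * (1 + gobj))
  }
})

test_that("two-step driver: feasible problems calibrate with zero budget", {
  res <- go_calibrate(intro_example())
  expect_identical(res$modification$branch, "feasible")
  expect_equal(res$achieved_tae, 0, tolerance = 1e-6)
  expect_equal(sum(res$w), 2016, tolerance = 1e-6)
})

test_that("two-step driver: infeasible problems get the certified budget", {
  res <- go_calibrate(intro_example(u = 20))
  expect_identical(res$modification$branch, "min_tae")
  expect_equal(res$modification$tae_star, 16, tolerance = 1e-6)
  expect_equal(res$w, rep(20, 100), tolerance = 1e-6)
})

test_that("driver reports incompatible exact constraints as an error", {
  X <- cbind(rep(1, 3), c(1, 0, 0))
  pr <- as_problem(X, d = rep(1, 3), t_x = c(10, 5), l = 0, u = 3,
                   exact = c(TRUE, FALSE))
  expect_error(go_calibrate(pr), "incompatible")
})

test_that("bound-change driver reduces to the two-step driver at eps = Inf", {
  pr <- intro_example(u = 20, U = 40)
  a1 <- go_calibrate(pr)
  a2 <- go_calibrate_relaxed(pr, eps = Inf)
  expect_identical(a2$modification$branch, "no_rr_change")
  expect_equal(a2$w, a1$w, tolerance = 1e-9)
  expect_equal(a2$distance, a1$distance, tolerance = 1e-9)
})

test_that("bound-change driver: zero tolerance relaxes bounds optimally", {
  res <- go_calibrate_relaxed(intro_example(u = 20, U = 40), eps = 0)
  expect_identical(res$modification$branch, "min_tac")
  expect_equal(res$modification$tac_star, 16, tolerance = 1e-5)
  expect_equal(sum(res$w), 2016, tolerance = 1e-4)
  expect_lte(res$achieved_tae, 1e-4)
})

test_that("bound-change driver falls back to TAE** when eps is unreachable", {
  res <- go_calibrate_relaxed(intro_example(u = 20, U = 20.1), eps = 0)
  expect_identical(res$modification$branch, "eps_substituted_tae_limit")
  expect_equal(res$modification$eps_used, 6, tolerance = 1e-5)
  expect_lte(res$achieved_tae, 6 * (1 + 1e-6) + 1e-6)
})

test_that("achieved distance is nonincreasing in the error budget", {
  pr <- intro_example()
  dist <- vapply(c(0, 4, 8, 16), function(b)
    solve_restricted(pr, b)$distance, numeric(1))
  expect_true(all(diff(dist) <= 1e-8))
})

test_that("a Gelman ratio bound is enforced on the calibrated weights", {
  set.seed(41)
  s <- sample_data(data.frame(unit_id = 1:30, weight = runif(30, 1, 2),
                              x = rnorm(30, 5)))
  pr <- calibration_problem(s, benchmark_spec("x", NA, 170),
                            range_restrictions(l = 0, u = Inf),
                            kappa_gb = 2)
  res <- go_calibrate(pr)
  expect_lte(max(res$w) / min(res$w), 2 + 1e-6)
})

test_that("design weights are a fixpoint when already calibrated", {
  s <- toy_survey()
  bm <- benchmark_spec(c("gender", "gender"), c("F", "M"),
                       c(5, 7))  # X'd = (2+2+1, 3+3+1) = (5, 7)
  pr <- calibration_problem(s, bm, range_restrictions(l = 0, u = 10))
  expect_equal(go_calibrate(pr)$w, s$d, tolerance = 1e-7)
  expect_equal(go_calibrate_relaxed(pr, eps = 3)$w, s$d, tolerance = 1e-7)
})
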
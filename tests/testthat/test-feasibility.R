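# Feasibility layer: minimum benchmark error (TAE*, TAE**), minimum bound
# change (TAC*), certificates and monotonicity, with exhaustive-search
# oracles on tiny instances.

test_that("the 100-unit worked example gives TAE* = 16 at bounds [0, 20]", {
  rep <- min_tae(intro_example(u = 20))
  expect_equal(rep$tae_star, 16, tolerance = 1e-7)
  expect_false(rep$feasible)
  # witness invariants: box respected, errors consistent with the optimum
  expect_true(all(rep$witness_w >= -1e-8 & rep$witness_w <= 20 + 1e-8))
  expect_equal(sum(rep$eps_tilde), rep$tae_star, tolerance = 1e-6)
})

test_that("feasibility flips with the upper bound as in the worked example", {
  expect_true(assess_feasibility(intro_example())$feasible)   # u = Inf
  expect_false(assess_feasibility(intro_example(u = 20))$feasible)
  expect_true(assess_feasibility(intro_example(u = 20.16))$feasible)
})

test_that("targets attainable at a bound give TAE* = 0 with witness at it", {
  X <- matrix(c(1, 0, 1, 1, 2, 0), 3, 2)
  l <- c(1, 2, 3)
  pr <- as_problem(X, d = rep(1, 3), t_x = as.vector(crossprod(X, l)),
                   l = l, u = l + 5)
  rep <- min_tae(pr)
  expect_equal(rep$tae_star, 0, tolerance = 1e-7)
  expect_equal(rep$witness_w, l, tolerance = 1e-5)
})

test_that("three-unit instance matches exhaustive search (TAE* = 3)", {
  X <- cbind(rep(1, 3), c(1, 0, 0))
  pr <- as_problem(X, d = rep(1, 3), t_x = c(10, 5), l = 0, u = 3)
  rep <- min_tae(pr)
  expect_equal(rep$tae_star, 3, tolerance = 1e-7)
  bf <- brute_tae(X, c(10, 5), c(1, 1), rep(0, 3), rep(3, 3), 31L)
  expect_equal(bf, 3)
})

test_that("TAE* equals the grid oracle on random tiny instances", {
  for (k in 1:12) {
    prm <- random_tiny_problem(n = sample(2:4, 1), p = sample(1:2, 1),
                               seed = 300 + k)
    pr <- as_problem(prm$X, prm$d, prm$t_x, l = prm$l, u = prm$u)
    got <- min_tae(pr)$tae_star
    m <- c(`2` = 41L, `3` = 21L, `4` = 11L)[as.character(nrow(prm$X))]
    bf <- brute_tae(prm$X, prm$t_x, prm$r, prm$l, prm$u, m)
    h <- max((prm$u - prm$l) / (m - 1))
    expect_gte(bf, got - 1e-6 * (1 + got))
    expect_lte(got, bf + tae_lipschitz(prm$X, prm$r) * h + 1e-7)
  }
})

test_that("largest-error mode equals brute-force minimax on tiny instances", {
  for (k in 1:6) {
    prm <- random_tiny_problem(n = 3, p = 2, seed = 500 + k)
    pr <- as_problem(prm$X, prm$d, prm$t_x, l = prm$l, u = prm$u,
                     norm = "linf")
    got <- min_tae(pr)$tae_star
    bf <- brute_tae_linf(prm$X, prm$t_x, prm$l, prm$u, 21L)
    h <- max((prm$u - prm$l) / 20)
    expect_gte(bf, got - 1e-6 * (1 + got))
    expect_lte(got, bf + tae_lipschitz(prm$X, prm$r) * h + 1e-7)
  }
})

test_that("widening the box never increases TAE*; TAE** <= TAE*", {
  for (k in 1:8) {
    prm <- random_tiny_problem(n = 4, p = 2, seed = 700 + k)
    pr <- as_problem(prm$X, prm$d, prm$t_x, l = prm$l, u = prm$u,
                     L = prm$l - 1, U = prm$u + 2)
    tae <- min_tae(pr)$tae_star
    wide <- as_problem(prm$X, prm$d, prm$t_x, l = prm$l, u = prm$u + 2)
    expect_lte(min_tae(wide)$tae_star, tae * (1 + 1e-6) + 1e-6)
    expect_lte(min_tae_at_limits(pr)$tae_star, tae * (1 + 1e-6) + 1e-6)
  }
})

test_that("identical inner and limiting boxes give TAE** = TAE*", {
  pr <- intro_example(u = 20)  # L, U default to l, u
  expect_equal(min_tae_at_limits(pr)$tae_star, min_tae(pr)$tae_star,
               tolerance = 1e-6)
})

test_that("worked example at limits: TAE** = 0 for U = 40, 6 for U = 20.1", {
  expect_equal(min_tae_at_limits(intro_example(u = 20, U = 40))$tae_star,
               0, tolerance = 1e-6)
  expect_equal(min_tae_at_limits(intro_example(u = 20, U = 20.1))$tae_star,
               6, tolerance = 1e-6)
})

test_that("min_tac covers the trivial, active and unattainable branches", {
  pr <- intro_example(u = 20, U = 40)
  # active: eps = 0 forces the upper bounds to absorb all 16 units
  rel <- min_tac(pr, eps = 0)
  expect_equal(rel$tac_star, 16, tolerance = 1e-6)
  expect_true(all(rel$lam >= -1e-9 & rel$lam <= pr$l - pr$L + 1e-9))
  expect_true(all(rel$mu >= -1e-9 & rel$mu <= pr$U - pr$u + 1e-9))
  expect_true(all(rel$witness_w >= rel$new_l - 1e-7 &
                    rel$witness_w <= rel$new_u + 1e-7))
  expect_equal(rel$tac_star, sum(rel$lam) + sum(rel$mu), tolerance = 1e-6)
  # trivial: tolerance at (or above) TAE*
  expect_equal(min_tac(pr, eps = 16)$tac_star, 0)
  expect_equal(min_tac(intro_example(), eps = 0)$tac_star, 0)  # feasible
  # unattainable: below TAE** even at the limits
  rel3 <- min_tac(intro_example(u = 20, U = 20.1), eps = 0)
  expect_identical(rel3$status, "eps_below_TAE_star_limit")
  expect_equal(rel3$tae_star_limit, 6, tolerance = 1e-6)
})

test_that("raising eps never increases TAC*", {
  pr <- intro_example(u = 20, U = 40)
  tacs <- vapply(c(0, 4, 8, 12, 16), function(e) min_tac(pr, e)$tac_star,
                 numeric(1))
  expect_true(all(diff(tacs) <= 1e-6))
  expect_equal(tacs, 16 - c(0, 4, 8, 12, 16), tolerance = 1e-6)
})

test_that("uniform and positivity-fixed relaxation modes work", {
  # one shared upper shift: the smallest uniform cap is 20.16
  rel <- min_tac(intro_example(u = 20, U = Inf), eps = 0,
                 uniform = TRUE, fix_lower = TRUE)
  expect_equal(unique(rel$mu), 0.16, tolerance = 1e-6)
  expect_equal(rel$new_u[1], 20.16, tolerance = 1e-6)
  expect_equal(sum(rel$lam), 0)
})

test_that("incompatible exact constraints surface as infeasible status", {
  X <- cbind(rep(1, 3), c(1, 0, 0))
  pr <- as_problem(X, d = rep(1, 3), t_x = c(10, 5), l = 0, u = 3,
                   exact = c(TRUE, FALSE))
  rep <- min_tae(pr)   # max attainable total is 9 < 10
  expect_identical(rep$status, "infeasible_exact_constraints")
  expect_false(rep$feasible)
  expect_identical(rep$tae_star, Inf)
})

test_that("per-constraint error caps bound individual errors", {
  # totals (9, 0) over [0,3]^3: any split has total error 3, but the cap
  # reroutes it away from the second constraint
  s <- data.frame(unit_id = 1:3, weight = 1, x1 = 1, x2 = c(1, 0, 0))
  bm <- benchmark_spec(c("x1", "x2"), NA, c(9, 0), eps_cap = c(NA, 1))
  pr <- calibration_problem(sample_data(s), bm,
                            range_restrictions(l = 0, u = 3))
  rep <- min_tae(pr)
  expect_lte(rep$eps_tilde[2], 1 + 1e-6)
  expect_equal(rep$tae_star, 3, tolerance = 1e-6)
  # a cap below what the box allows is a structural infeasibility
  bm2 <- benchmark_spec(c("x1", "x2"), NA, c(10, 5), eps_cap = c(NA, 0.5))
  pr2 <- calibration_problem(sample_data(s), bm2,
                             range_restrictions(l = 0, u = 3))
  expect_identical(min_tae(pr2)$status, "infeasible_exact_constraints")
})

test_that("feasibility is decided by the scale-free zero tolerance", {
  # a tiny residual well inside the tolerance still counts as feasible
  pr <- intro_example(u = 20.16)
  expect_true(assess_feasibility(pr)$feasible)
  # empty non-exact error set: exact-only problems report through prechecks
  pr2 <- intro_example(u = 20.16)
  pr2$exact <- TRUE
  pr2$spec$exact <- TRUE
  expect_true(min_tae(pr2)$feasible)
})
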
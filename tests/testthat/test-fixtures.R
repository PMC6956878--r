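# Scenario generator: determinism, structural guarantees, recovery of
# benchmarks at zero inconsistency, and the three-experiment design.

test_that("the built-in worked example is assembled as documented", {
  pr <- intro_example()
  expect_identical(nrow(validate_problem(pr)), 0L)
  expect_equal(sum(pr$d), 2000)
  expect_equal(pr$t_x, 2016)
  expect_equal(as.vector(Matrix::colSums(pr$X)), 100)
})

test_that("scenarios are a pure function of the seed", {
  a <- generate_scenario(population_size = 4000, sample_size = 150, seed = 5)
  b <- generate_scenario(population_size = 4000, sample_size = 150, seed = 5)
  expect_identical(a$fine_benchmarks$total, b$fine_benchmarks$total)
  expect_identical(a$sample$unit_id, b$sample$unit_id)
  expect_identical(a$validation_table$total, b$validation_table$total)
  c2 <- generate_scenario(population_size = 4000, sample_size = 150, seed = 6)
  expect_false(identical(a$sample$unit_id, c2$sample$unit_id))
})

test_that("benchmark tables tabulate the population before perturbation", {
  sc <- generate_scenario(population_size = 3000, sample_size = 100,
                          delta = 0, zero_cell = FALSE, seed = 11,
                          n_fine_age = 4, n_broad_age = 2)
  pop <- sc$population
  key <- paste(pop$region, pop$gender, pop$age_band)
  tab <- table(factor(key, levels = paste(sc$fine_truth$region,
                                          sc$fine_truth$gender,
                                          sc$fine_truth$age_band)))
  expect_equal(as.vector(tab), sc$fine_truth$total)
  expect_equal(sc$fine_benchmarks$total, as.numeric(sc$fine_truth$total))
  expect_equal(sum(sc$broad_benchmarks$total[1:4]), nrow(pop))
})

test_that("zero-cell control adds or forbids empty benchmarked cells", {
  sc <- generate_scenario(population_size = 20000, sample_size = 300,
                          zero_cell = TRUE, seed = 3)
  v <- paste(sc$sample$variables$region, sc$sample$variables$gender,
             sc$sample$variables$age_band)
  k <- paste(sc$fine_truth$region, sc$fine_truth$gender,
             sc$fine_truth$age_band)
  counts <- tabulate(match(v, k), nbins = length(k))
  expect_true(any(counts == 0 & sc$fine_truth$total > 0))
  # and the LP lower bound: no weight mass can enter an empty cell
  bm <- c(sc$broad_benchmarks, sc$fine_benchmarks)
  pr <- calibration_problem(sc$sample, bm,
                            range_restrictions(l = 0, u = Inf))
  zero_mass <- sum(sc$fine_benchmarks$total[counts == 0])
  expect_gte(min_tae(pr)$tae_star, zero_mass * (1 - 1e-9) - 1e-6)
})

test_that("consistent benchmarks are recovered exactly from a sample", {
  sc <- generate_scenario(population_size = 5000, sample_size = 400,
                          n_fine_age = 4, n_broad_age = 2,
                          concentration = 5, delta = 0,
                          zero_cell = FALSE, seed = 17)
  bm <- c(sc$broad_benchmarks, sc$fine_benchmarks)
  pr <- calibration_problem(sc$sample, bm,
                            range_restrictions(l = 0, u = Inf))
  res <- go_calibrate(pr)
  expect_identical(res$modification$branch, "feasible")
  expect_lte(res$achieved_tae, 1e-4)
  est <- as.vector(Matrix::crossprod(pr$X, res$w))
  expect_equal(est, c(bm$total), tolerance = 1e-6)
})

test_that("whole population as the sample calibrates to weights of one", {
  sc <- generate_scenario(population_size = 400, sample_size = 400,
                          n_fine_age = 2, n_broad_age = 2, n_regions = 2,
                          concentration = 5, delta = 0, zero_cell = FALSE,
                          seed = 23)
  bm <- c(sc$broad_benchmarks, sc$fine_benchmarks)
  pr <- calibration_problem(sc$sample, bm,
                            range_restrictions(l = 0, u = Inf))
  res <- go_calibrate(pr)
  expect_equal(res$w, rep(1, 400), tolerance = 1e-6)
})

test_that("stratified sampling yields inverse-inclusion weights", {
  sc <- generate_scenario(population_size = 6000, sample_size = 300,
                          stratified = TRUE, zero_cell = FALSE,
                          n_fine_age = 4, n_broad_age = 2,
                          concentration = 5, delta = 0, seed = 29)
  d <- sc$sample$d
  reg <- sc$sample$variables$region
  for (r in levels(reg)) {
    in_r <- reg == r
    expect_equal(unique(d[in_r]),
                 sum(sc$population$region == r) / sum(in_r))
  }
  expect_equal(sum(d), 6000, tolerance = 1e-9)
})

test_that("experiment battery preserves its ordering guarantees", {
  sc <- generate_scenario(population_size = 20000, sample_size = 400,
                          seed = 37)
  ex <- scenario_experiments(sc)
  s <- ex$summary
  # tighter bounds can only raise the minimum benchmark error
  expect_gte(s["Ex2", "tae_star"],
             s["Ex1", "tae_star"] * (1 - 1e-6) - 1e-6)
  # the bound-change run sits between the free run and max(Ex2, eps)
  expect_gte(s["Ex3", "fit_TAE"] + 1e-6 + 1e-6 * s["Ex3", "fit_TAE"],
             s["Ex1", "fit_TAE"])
  expect_lte(s["Ex3", "fit_TAE"],
             max(s["Ex2", "fit_TAE"], ex$eps) * (1 + 1e-6) + 1e-6)
  # the stated range restrictions force the Ex2 weight-ratio cap
  expect_lte(s["Ex2", "max_min_ratio"], 3.5 / 0.5 + 1e-9)
})

test_that("impossible zero-cell demands fail loudly", {
  expect_error(
    generate_scenario(population_size = 200, sample_size = 200,
                      zero_cell = TRUE, seed = 1, max_tries = 3),
    "could not obtain")
})
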
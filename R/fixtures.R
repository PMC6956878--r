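## Built-in worked example and deterministic census-versus-survey synthetic
## scenarios: a population cross-classified by region x gender x fine age
## band plus a non-benchmarked activity variable, a drawn sample, benchmark
## tables with optional multiplicative inconsistency, and a validation table
## of true totals.

#' The introductory 100-unit calibration example
#'
#' A sample of `n = 100` units with initial weights `d = 20`, a single
#' all-units benchmark constraint `w_1 + ... + w_100 = 2016`, and
#' configurable range restrictions. With positivity only (`u = Inf`) the
#' problem is feasible (e.g. all weights 20.16); capping the weights at 20
#' makes it infeasible with a minimum benchmark error of 16.
#'
#' @param u,l upper/lower weight bounds (scalar or length 100).
#' @param L,U optional limiting bounds (default: equal to `l` and `u`).
#' @return A [calibration_problem()] with 10 PSUs of 10 units each.
#' @examples
#' min_tae(intro_example(u = 20))$tae_star  # 16
#' @export
intro_example <- function(u = Inf, l = 0, L = NULL, U = NULL) {
  s <- sample_data(data.frame(
    unit_id = seq_len(100L),
    psu_id = rep(sprintf("P%02d", 1:10), each = 10L),
    weight = 20
  ))
  spec <- benchmark_spec("*", NA_character_, 2016)
  calibration_problem(s, spec, range_restrictions(l = l, u = u, L = L, U = U))
}

## deterministic activity profile: activity class correlated with age band
## (late classes concentrate in late bands, emulating e.g. retirement)
.activity_profile <- function(n_broad, n_activity) {
  prof <- outer(seq_len(n_broad), seq_len(n_activity), function(b, k) {
    exp(-((k - 1) / max(1, n_activity - 1) -
            (b - 1) / max(1, n_broad - 1))^2 / 0.08)
  })
  sweep(prof, 1L, rowSums(prof), "/")
}

#' Generate a synthetic census-calibration scenario
#'
#' Draws a population cross-classified by region, gender and a fine age
#' band (cell probabilities from a symmetric Dirichlet, so some cells are
#' rare), plus an activity class correlated with age that is never
#' benchmarked. A sample is drawn without replacement; benchmark tables are
#' tabulated from the population: a fine region x gender x age table used as
#' inexact constraints (optionally perturbed multiplicatively by independent
#' factors in `[1 - delta, 1 + delta]`, making the system inconsistent for
#' `delta > 0`) and broad gender x age-band and region tables used as exact
#' constraints. True totals of activity by broad band are kept for
#' validation only.
#'
#' Everything is deterministic given `seed`. With `zero_cell = TRUE` the
#' sample is redrawn until at least one fine cell with positive population
#' total has no sampled unit (the structural infeasibility the method is
#' designed for); with `zero_cell = FALSE`, until no such cell exists.
#'
#' @param population_size,sample_size population and sample sizes.
#' @param n_regions,n_fine_age,n_broad_age,n_activity category counts
#'   (`n_fine_age` must be a multiple of `n_broad_age`; gender is binary).
#' @param concentration symmetric-Dirichlet concentration for the fine-cell
#'   probabilities (smaller = more skewed cell sizes).
#' @param delta multiplicative perturbation half-width applied to the fine
#'   benchmark totals (`0` = fully consistent).
#' @param zero_cell require (or forbid) an empty-but-benchmarked fine cell.
#' @param stratified if `TRUE`, equal-allocation sampling by region with
#'   inverse-inclusion-probability weights; otherwise simple random sampling
#'   with `d = N/n`.
#' @param psus_per_region number of primary sampling units per region.
#' @param seed integer seed; the scenario is a pure function of it.
#' @param max_tries resampling attempts for the zero-cell condition.
#' @return Object of class `synthetic_scenario`: `population`, `sample`
#'   (a [sample_data()]), `broad_benchmarks` (exact), `fine_benchmarks`
#'   (inexact, perturbed), `fine_truth` (unperturbed totals),
#'   `validation_table`, `config`, `seed`.
#' @examples
#' sc <- generate_scenario(population_size = 5000, sample_size = 200,
#'                         delta = 0, zero_cell = FALSE, seed = 7)
#' sc$sample$n
#' @export
generate_scenario <- function(population_size = 100000L, sample_size = 1000L,
                              n_regions = 3L, n_fine_age = 12L,
                              n_broad_age = 4L, n_activity = 4L,
                              concentration = 2, delta = 0.02,
                              zero_cell = TRUE, stratified = FALSE,
                              psus_per_region = 20L, seed = 1L,
                              max_tries = 200L) {
  stopifnot(population_size >= sample_size, sample_size >= 1,
            n_regions >= 1, n_fine_age >= 1, n_broad_age >= 1,
            n_fine_age %% n_broad_age == 0, n_activity >= 1,
            concentration > 0, delta >= 0, delta < 1)
  config <- list(population_size = population_size,
                 sample_size = sample_size, n_regions = n_regions,
                 n_fine_age = n_fine_age, n_broad_age = n_broad_age,
                 n_activity = n_activity, concentration = concentration,
                 delta = delta, zero_cell = zero_cell,
                 stratified = stratified,
                 psus_per_region = psus_per_region, seed = seed)
  .with_seed(seed, {
    N <- as.integer(population_size)
    regions <- sprintf("R%d", seq_len(n_regions))
    genders <- c("F", "M")[seq_len(2L)]
    ages <- sprintf("A%02d", seq_len(n_fine_age))
    broads <- sprintf("B%d", seq_len(n_broad_age))
    acts <- sprintf("act%d", seq_len(n_activity))
    cells <- expand.grid(region = regions, gender = genders,
                         age_band = ages, KEEP.OUT.ATTRS = FALSE,
                         stringsAsFactors = FALSE)
    k <- nrow(cells)
    pr <- stats::rgamma(k, shape = concentration)
    pr <- pr / sum(pr)
    counts <- as.vector(stats::rmultinom(1L, N, pr))

    cell_of_unit <- rep(seq_len(k), counts)
    pop <- cells[cell_of_unit, , drop = FALSE]
    rownames(pop) <- NULL
    band_of_age <- rep(broads, each = n_fine_age / n_broad_age)
    pop$broad_band <- band_of_age[match(pop$age_band, ages)]
    prof <- .activity_profile(n_broad_age, n_activity)
    bidx <- match(pop$broad_band, broads)
    u01 <- stats::runif(N)
    cum <- t(apply(prof, 1L, cumsum))
    pop$activity <- acts[max.col(cum[bidx, , drop = FALSE] >= u01,
                                 ties.method = "first")]
    ## PSUs: units scattered over clusters within their region
    pop$psu_id <- paste0(pop$region, "_P",
                         sprintf("%02d", sample.int(psus_per_region, N,
                                                    replace = TRUE)))
    for (cn in c("region", "gender", "age_band", "broad_band", "activity")) {
      pop[[cn]] <- factor(pop[[cn]],
                          levels = switch(cn, region = regions,
                                          gender = genders, age_band = ages,
                                          broad_band = broads,
                                          activity = acts))
    }

    draw_sample <- function() {
      if (stratified) {
        n_r <- rep(sample_size %/% n_regions, n_regions)
        extra <- sample_size - sum(n_r)
        if (extra > 0) n_r[seq_len(extra)] <- n_r[seq_len(extra)] + 1L
        idx <- unlist(lapply(seq_len(n_regions), function(r) {
          pool <- which(pop$region == regions[r])
          if (length(pool) < n_r[r]) {
            stop("generate_scenario: region ", regions[r],
                 " smaller than its stratified allocation")
          }
          sample(pool, n_r[r])
        }))
        d <- numeric(length(idx))
        for (r in seq_len(n_regions)) {
          in_r <- pop$region[idx] == regions[r]
          d[in_r] <- sum(pop$region == regions[r]) / sum(in_r)
        }
        list(idx = idx, d = d)
      } else {
        idx <- sample.int(N, sample_size)
        list(idx = idx, d = rep(N / sample_size, sample_size))
      }
    }
    fine_pop <- counts  # population totals in the order of `cells`
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      sm <- draw_sample()
      scount <- tabulate(cell_of_unit[sm$idx], nbins = k)
      has_zero <- any(scount == 0L & fine_pop > 0L)
      if (zero_cell == has_zero) { ok <- TRUE; break }
    }
    if (!ok) {
      stop("generate_scenario: could not ", if (zero_cell) "obtain" else
        "avoid", " an empty benchmarked cell in ", max_tries, " draws; ",
        "adjust sizes or the concentration")
    }
    sdf <- pop[sm$idx, , drop = FALSE]
    sdf$unit_id <- sprintf("U%06d", sm$idx)
    sdf$weight <- sm$d
    rownames(sdf) <- NULL
    sample <- sample_data(sdf)

    ## benchmark tables tabulated from the population
    fine_perturbed <- fine_pop * stats::runif(k, 1 - delta, 1 + delta)
    fine_bm <- benchmark_spec(
      variables = "region;gender;age_band",
      categories = paste(cells$region, cells$gender, cells$age_band,
                         sep = ";"),
      total = fine_perturbed, exact = FALSE)
    gb <- expand.grid(gender = genders, broad_band = broads,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    gb$total <- mapply(function(g, b) {
      sum(pop$gender == g & pop$broad_band == b)
    }, gb$gender, gb$broad_band)
    reg_tot <- vapply(regions, function(r) sum(pop$region == r), numeric(1))
    broad_bm <- c(
      benchmark_spec("gender;broad_band",
                     paste(gb$gender, gb$broad_band, sep = ";"),
                     gb$total, exact = TRUE),
      benchmark_spec("region", regions, as.numeric(reg_tot), exact = TRUE)
    )
    val <- expand.grid(broad_band = broads, activity = acts,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    val$total <- mapply(function(b, a) {
      sum(pop$broad_band == b & pop$activity == a)
    }, val$broad_band, val$activity)
    fine_truth <- cells
    fine_truth$total <- fine_pop

    structure(list(population = pop, sample = sample,
                   broad_benchmarks = broad_bm, fine_benchmarks = fine_bm,
                   fine_truth = fine_truth, validation_table = val,
                   config = config, seed = seed),
              class = "synthetic_scenario")
  })
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat("<synthetic_scenario> N =", nrow(x$population),
      " n =", x$sample$n,
      " fine cells =", nrow(x$fine_benchmarks),
      " (delta =", x$config$delta, ")\n")
  invisible(x)
}

## indicator matrix of the validation cross-classification for a sample
.validation_design <- function(sample, val) {
  vals <- paste(sample$variables$broad_band, sample$variables$activity)
  keys <- paste(val$broad_band, val$activity)
  out <- matrix(0, sample$n, nrow(val), dimnames = list(NULL, keys))
  out[cbind(seq_len(sample$n), match(vals, keys))] <- 1
  out
}

#' Run the three-experiment calibration design on a scenario
#'
#' The standard evaluation layout: broad benchmarks imposed exactly
#' throughout, the fine cross-tabulation as inexact constraints, and three
#' range-restriction regimes —
#' `Ex1` positivity only (`w >= 0`) at minimum benchmark error;
#' `Ex2` user bounds `0.5 d <= w <= 3.5 d` at minimum benchmark error;
#' `Ex3` minimum change of the `Ex2` bounds inside limits `[0, 10 d]` such
#' that the benchmark error stays below `eps_pct` percent of the population
#' size. A Horvitz-Thompson row (initial weights, no calibration) is
#' included as the reference.
#'
#' @param scenario a [generate_scenario()] result.
#' @param eps_pct error tolerance for `Ex3`, percent of population size.
#' @param jackknife_G optional number of delete-a-group jackknife groups;
#'   when given, average standard deviations of the fine-benchmark and
#'   validation estimates are computed for the rows in `jackknife_for`.
#' @param jackknife_for rows to jackknife (subset of
#'   `c("HT", "Ex1", "Ex2", "Ex3")`).
#' @param jackknife_seed seed for the PSU-to-group shuffle.
#' @return Object of class `scenario_experiments`: `summary` (one row per
#'   weight set: weight diagnostics, benchmark-fit metrics, validation
#'   metrics, modification record), `results` (the `calibration_result`s),
#'   `jackknife` (average SDs, when requested).
#' @export
scenario_experiments <- function(scenario, eps_pct = 0.1,
                                 jackknife_G = NULL,
                                 jackknife_for = c("HT", "Ex1"),
                                 jackknife_seed = 1L) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  bm <- c(scenario$broad_benchmarks, scenario$fine_benchmarks)
  p_broad <- nrow(scenario$broad_benchmarks)
  fine_idx <- p_broad + seq_len(nrow(scenario$fine_benchmarks))
  smp <- scenario$sample
  N <- nrow(scenario$population)
  eps <- eps_pct / 100 * N

  problems <- list(
    Ex1 = calibration_problem(smp, bm, range_restrictions(l = 0, u = Inf)),
    Ex2 = calibration_problem(smp, bm,
      range_restrictions(l = 0.5, u = 3.5, mode = "relative")),
    Ex3 = calibration_problem(smp, bm,
      range_restrictions(l = 0.5, u = 3.5, L = 0, U = 10,
                         mode = "relative"))
  )
  results <- list(
    Ex1 = go_calibrate(problems$Ex1),
    Ex2 = go_calibrate(problems$Ex2),
    Ex3 = go_calibrate_relaxed(problems$Ex3, eps = eps)
  )
  X <- problems$Ex1$X
  Y_val <- .validation_design(smp, scenario$validation_table)
  weights <- c(list(HT = smp$d), lapply(results, `[[`, "w"))

  rows <- lapply(names(weights), function(nm) {
    w <- weights[[nm]]
    diag <- weight_diagnostics(w, smp$d)
    fit_est <- as.vector(Matrix::crossprod(X[, fine_idx, drop = FALSE], w))
    fit <- error_metrics(fit_est, scenario$fine_benchmarks$total, N)
    vest <- estimate_totals(Y_val, w)
    vm <- error_metrics(vest, scenario$validation_table$total, N)
    data.frame(experiment = nm,
               chi_sq = diag$chi_sq, min = diag$min, Q1 = diag$Q1,
               median = diag$median, Q3 = diag$Q3, max = diag$max,
               max_min_ratio = diag$max_min_ratio,
               fit_TAE = fit$TAE, fit_TAE_pct = fit$TAE_pct,
               fit_TRE_pct = fit$TRE_pct, fit_RMSE = fit$RMSE,
               val_TAE = vm$TAE, val_TAE_pct = vm$TAE_pct,
               val_TRE_pct = vm$TRE_pct, val_RMSE = vm$RMSE,
               tae_star = if (nm == "HT") NA_real_ else
                 results[[nm]]$modification$tae_star,
               tac_star = if (nm %in% c("HT", "Ex1", "Ex2")) NA_real_ else
                 results[[nm]]$modification$tac_star,
               stringsAsFactors = FALSE)
  })
  summary <- do.call(rbind, rows)
  rownames(summary) <- summary$experiment

  jack <- NULL
  if (!is.null(jackknife_G)) {
    plan <- jackknife_plan(smp$psu_id, jackknife_G, seed = jackknife_seed)
    pipelines <- list(
      HT = function(s) {
        Xs <- build_design_matrix(s, scenario$fine_benchmarks)
        c(as.vector(Matrix::crossprod(Xs, s$d)),
          estimate_totals(.validation_design(s, scenario$validation_table),
                          s$d))
      },
      Ex1 = .recal_pipeline(scenario, bm, fine_idx,
                            range_restrictions(l = 0, u = Inf)),
      Ex2 = .recal_pipeline(scenario, bm, fine_idx,
        range_restrictions(l = 0.5, u = 3.5, mode = "relative")),
      Ex3 = .recal_pipeline(scenario, bm, fine_idx,
        range_restrictions(l = 0.5, u = 3.5, L = 0, U = 10,
                           mode = "relative"), eps = eps)
    )
    jack <- lapply(pipelines[intersect(jackknife_for, names(pipelines))],
                   function(pl) {
      jk <- jackknife_sd(smp, plan, pl)
      n_fine <- nrow(scenario$fine_benchmarks)
      list(sd_fine_avg = mean(jk$sd[seq_len(n_fine)]),
           sd_val_avg = mean(jk$sd[-seq_len(n_fine)]),
           n_failed = jk$n_failed)
    })
  }
  structure(list(summary = summary, results = results, jackknife = jack,
                 problems = problems, eps = eps,
                 config = scenario$config),
            class = "scenario_experiments")
}

## replicate pipeline: recalibrate the reweighted subsample, then estimate
## the fine-benchmark and validation totals
.recal_pipeline <- function(scenario, bm, fine_idx, rr, eps = NULL) {
  force(rr); force(eps)
  function(s) {
    pr <- calibration_problem(s, bm, rr)
    res <- if (is.null(eps)) go_calibrate(pr) else
      go_calibrate_relaxed(pr, eps = eps)
    c(as.vector(Matrix::crossprod(pr$X[, fine_idx, drop = FALSE], res$w)),
      estimate_totals(.validation_design(s, scenario$validation_table),
                      res$w))
  }
}

#' @export
print.scenario_experiments <- function(x, ...) {
  cat("<scenario_experiments> eps =", format(x$eps), "\n")
  print(x$summary[, c("experiment", "chi_sq", "min", "max",
                      "max_min_ratio", "fit_TAE_pct", "val_TAE_pct",
                      "tae_star", "tac_star")], digits = 4)
  invisible(x)
}
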
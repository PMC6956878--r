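## Calibration estimation of totals, delete-a-group jackknife standard
## deviations over primary sampling units, fitting-error metrics, and
## weight-distribution diagnostics.

#' Weighted estimates of population totals
#'
#' `t_y = Y'w`: with the initial weights this is the Horvitz-Thompson
#' estimator; with calibrated weights, the calibration estimator.
#'
#' @param Y numeric vector, matrix or data.frame of target-variable values,
#'   one row per sampled unit.
#' @param w weight vector (length = rows of `Y`).
#' @return Named numeric vector of totals, one per column of `Y`.
#' @examples
#' estimate_totals(cbind(a = c(1, 0, 1), b = c(0, 1, 1)), c(2, 3, 4))
#' @export
estimate_totals <- function(Y, w) {
  Y <- as.matrix(Y)
  if (nrow(Y) != length(w)) {
    stop("estimate_totals: Y has ", nrow(Y), " rows but w has length ",
         length(w))
  }
  drop(crossprod(Y, w))
}

## evaluate expr with a temporary RNG state seeded by `seed`
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Delete-a-group jackknife replication plan
#'
#' Partitions the primary sampling units into `G` replicate groups:
#' systematic assignment after a seeded random shuffle, so every PSU lands
#' in exactly one group and group sizes differ by at most one.
#'
#' @param psu_ids vector of PSU identifiers, one per sampled unit.
#' @param G number of replicate groups (`2 <= G <=` number of PSUs).
#' @param seed integer seed for the shuffle (recorded in the plan).
#' @return Object of class `jackknife_plan`: `G`, `groups` (named map PSU ->
#'   group), `seed`.
#' @export
jackknife_plan <- function(psu_ids, G, seed = 1L) {
  psus <- unique(as.character(psu_ids))
  G <- as.integer(G)
  if (G < 2L) stop("jackknife_plan: need G >= 2 groups")
  if (G > length(psus)) {
    stop("jackknife_plan: G = ", G, " exceeds the ", length(psus),
         " distinct PSUs")
  }
  shuffled <- .with_seed(seed, sample(psus))
  groups <- stats::setNames(rep_len(seq_len(G), length(psus)), shuffled)
  structure(list(G = G, groups = groups, seed = seed),
            class = "jackknife_plan")
}

#' Delete-a-group jackknife standard deviations
#'
#' For each replicate group the units of its PSUs are deleted, the remaining
#' initial weights are rescaled by `G/(G-1)`, and the full estimation
#' pipeline (typically recalibration plus totals) is rerun. The reported
#' standard deviation per estimate is
#' `sqrt((G-1)/G * sum_g (theta_g - theta_full)^2)`,
#' with `theta_full` from the complete sample. Replicates whose pipeline
#' fails structurally are excluded and counted.
#'
#' @param sample a [sample_data()] with PSU identifiers.
#' @param plan a [jackknife_plan()].
#' @param pipeline function taking a `sample_data` and returning a named
#'   numeric vector of estimates; must be deterministic given its input.
#' @return list with `sd` (per estimate), `estimates` (full-sample),
#'   `replicates` (G x r matrix, failed rows `NA`), `n_failed`, `plan`.
#' @export
jackknife_sd <- function(sample, plan, pipeline) {
  stopifnot(inherits(sample, "sample_data"),
            inherits(plan, "jackknife_plan"), is.function(pipeline))
  if (is.null(sample$psu_id)) stop("jackknife_sd: sample has no PSU ids")
  G <- plan$G
  theta_full <- pipeline(sample)
  reps <- matrix(NA_real_, G, length(theta_full),
                 dimnames = list(NULL, names(theta_full)))
  unit_group <- unname(plan$groups[as.character(sample$psu_id)])
  if (anyNA(unit_group)) {
    stop("jackknife_sd: sample contains PSUs absent from the plan")
  }
  for (g in seq_len(G)) {
    keep <- which(unit_group != g)
    if (!length(keep)) next
    rep_est <- tryCatch(
      pipeline(.subset_sample(sample, keep, d_scale = G / (G - 1))),
      error = function(e) NULL)
    if (!is.null(rep_est)) reps[g, ] <- rep_est
  }
  ok <- stats::complete.cases(reps)
  n_failed <- sum(!ok)
  if (n_failed) {
    warning("jackknife_sd: ", n_failed, " replicate(s) failed and were ",
            "excluded")
  }
  dev2 <- sweep(reps[ok, , drop = FALSE], 2L, theta_full)^2
  sd <- sqrt((G - 1) / G * colSums(dev2))
  list(sd = sd, estimates = theta_full, replicates = reps,
       n_failed = n_failed, plan = plan)
}

#' Fitting-error metrics for estimated totals
#'
#' Standard error summaries for a vector of estimated totals against
#' reference values: `TAE` (total absolute error), `TAE_pct` (as a
#' percentage of the population size `N`), `TRE_pct` (total relative error,
#' the sum of per-cell relative errors as a percentage, over cells with
#' positive reference value; zero-reference cells are excluded and counted),
#' and `RMSE`.
#'
#' @param estimates,truths numeric vectors of equal length.
#' @param N population total (> 0) used to scale `TAE_pct`.
#' @return list `TAE`, `TAE_pct`, `TRE_pct`, `RMSE`, `n_zero_truth_excluded`.
#' @examples
#' error_metrics(c(10, 20), c(12, 18), N = 30)
#' @export
error_metrics <- function(estimates, truths, N) {
  stopifnot(length(estimates) == length(truths))
  if (!is.numeric(N) || length(N) != 1L || N <= 0) {
    stop("error_metrics: N must be a positive scalar")
  }
  ae <- abs(estimates - truths)
  pos <- truths > 0
  list(
    TAE = sum(ae),
    TAE_pct = 100 * sum(ae) / N,
    TRE_pct = 100 * sum(ae[pos] / truths[pos]),
    RMSE = sqrt(mean((estimates - truths)^2)),
    n_zero_truth_excluded = sum(!pos)
  )
}

#' Weight-distribution diagnostics
#'
#' Chi-square distance to the initial weights (raw, and averaged per unit)
#' plus distribution statistics of the weights: minimum, quartiles (linear
#' interpolation between order statistics), maximum, and the max/min ratio
#' (`Inf` when the minimum is nonpositive).
#'
#' @inheritParams chi_square_distance
#' @return list `chi_sq`, `chi_sq_per_unit`, `min`, `Q1`, `median`, `Q3`,
#'   `max`, `max_min_ratio`.
#' @examples
#' weight_diagnostics(c(1, 2, 3, 4), rep(1, 4))
#' @export
weight_diagnostics <- function(w, d) {
  if (!length(w)) stop("weight_diagnostics: empty weight vector")
  qs <- stats::quantile(w, c(0, 0.25, 0.5, 0.75, 1), names = FALSE, type = 7)
  list(
    chi_sq = chi_square_distance(w, d),
    chi_sq_per_unit = chi_square_distance(w, d) / length(w),
    min = qs[1], Q1 = qs[2], median = qs[3], Q3 = qs[4], max = qs[5],
    max_min_ratio = if (qs[1] <= 0) Inf else qs[5] / qs[1]
  )
}
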
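## Chi-square-distance calibration: the GREG closed form, the globally
## optimal bound-and-l1-ball quadratic program, and the two always-convergent
## calibration drivers (minimum benchmark error; minimum bound change).

#' Modified chi-square (GREG) distance between weight vectors
#'
#' `sum_i (w_i - d_i)^2 / d_i`, the generalised least squares distance whose
#' unconstrained benchmark-calibrated minimiser is the generalised
#' regression (GREG) weight vector.
#'
#' @param w candidate weights.
#' @param d initial weights, all strictly positive.
#' @return A nonnegative scalar; zero iff `w == d`.
#' @examples
#' chi_square_distance(c(1, 2, 3, 4), rep(1, 4))  # 14
#' @export
chi_square_distance <- function(w, d) {
  stopifnot(length(w) == length(d))
  if (any(d <= 0)) stop("chi_square_distance: d must be strictly positive")
  sum((w - d)^2 / d)
}

#' Modified discrimination information (raking) distance
#'
#' `sum_i w_i log(w_i / d_i) - w_i + d_i`, the distance minimised by raking.
#' Provided for evaluating and comparing weight sets; the package's solvers
#' minimise the chi-square distance.
#'
#' @inheritParams chi_square_distance
#' @return A nonnegative scalar. A zero weight contributes `d_i` (the limit
#'   `w log w -> 0` as `w -> 0`).
#' @examples
#' mdi_distance(exp(1), 1)  # 1
#' @export
mdi_distance <- function(w, d) {
  stopifnot(length(w) == length(d))
  if (any(d <= 0)) stop("mdi_distance: d must be strictly positive")
  if (any(w < 0)) stop("mdi_distance: w must be nonnegative")
  term <- ifelse(w > 0, w * log(w / d) - w + d, d)
  sum(term)
}

#' Generalised regression (GREG) calibration weights, closed form
#'
#' The unrestricted minimiser of the chi-square distance subject to the
#' benchmark constraints `X'w = t_x`:
#' `w = d + D X (X'DX)^-1 (t_x - X'd)` with `D = diag(d)`.
#'
#' @param X `n x p` benchmark matrix (dense or sparse).
#' @param d initial weights (> 0).
#' @param t_x benchmark totals (length `p`).
#' @return Weight vector of length `n` satisfying `X'w = t_x`.
#' @examples
#' greg_weights(matrix(1, 100, 1), rep(20, 100), 2016)[1]  # 20.16
#' @export
greg_weights <- function(X, d, t_x) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(d), ncol(X) == length(t_x))
  if (any(d <= 0)) stop("greg_weights: d must be strictly positive")
  M <- crossprod(X, X * d)
  qrM <- qr(M)
  if (qrM$rank < ncol(X)) {
    dep <- qrM$pivot[seq.int(qrM$rank + 1L, ncol(X))]
    labs <- if (!is.null(colnames(X))) colnames(X)[dep] else dep
    stop("greg_weights: X'DX is singular; collinear constraint(s): ",
         paste(labs, collapse = ", "))
  }
  lam <- solve(qrM, t_x - as.vector(crossprod(X, d)))
  as.vector(d + d * (X %*% lam))
}

#' Globally optimal calibration inside an error budget
#'
#' Minimises the chi-square distance to the initial weights subject to the
#' range restrictions, the exact benchmark constraints as equalities, and
#' the non-exact constraints relaxed into the weighted l1 ball
#' `sum_j r_j |X_j'w - t_j| <= tae_budget` (in `"linf"` norm mode, a cap on
#' the largest error instead). The l1 ball is linearised with nonnegative
#' auxiliary error variables, giving a convex quadratic program solved to
#' global optimality.
#'
#' The caller must supply a feasible budget — in practice the value
#' certified by [min_tae()] (this is what [go_calibrate()] automates).
#'
#' @param problem a [calibration_problem()].
#' @param tae_budget nonnegative error budget; `0` turns all constraints
#'   into equalities.
#' @param bounds_override optional `list(l = , u = )` of per-unit bounds to
#'   use instead of the problem's (e.g. bounds relaxed by [min_tac()]).
#' @return An object of class `calibration_result`: weights `w`, `distance`,
#'   `per_constraint_error` (`X'w - t_x`), `achieved_tae`,
#'   `tae_budget_used`, the enforced bounds `applied_l`/`applied_u`, a
#'   `modification` record and the solver `status`.
#' @examples
#' res <- solve_restricted(intro_example(), tae_budget = 0)
#' res$w[1]  # 20.16
#' @export
solve_restricted <- function(problem, tae_budget, bounds_override = NULL) {
  stopifnot(inherits(problem, "calibration_problem"),
            is.numeric(tae_budget), length(tae_budget) == 1L,
            tae_budget >= 0)
  l <- if (is.null(bounds_override)) problem$l else bounds_override$l
  u <- if (is.null(bounds_override)) problem$u else bounds_override$u
  n <- problem$n
  tol <- .feastol(problem)

  zero_budget <- tae_budget <= 0
  exact_eff <- if (zero_budget) rep(TRUE, problem$p) else problem$exact
  asm <- .assemble(problem, l, u, exact_override = exact_eff)
  nv <- asm$nv
  A_in <- asm$A_in; b_in <- asm$b_in
  if (!zero_budget && length(asm$i_eps)) {
    row <- numeric(nv)
    row[asm$i_eps] <- if (asm$linf) 1 else problem$r[asm$inx]
    if (asm$linf) {
      ## single shared error variable: cap it directly
      asm$ub[asm$i_eps] <- min(asm$ub[asm$i_eps], tae_budget)
    } else {
      A_in <- rbind(A_in, Matrix::Matrix(row, 1L, nv, sparse = TRUE))
      b_in <- c(b_in, tae_budget)
    }
  }
  q <- c(2 / problem$d, numeric(nv - n))
  cvec <- c(rep(-2, n), numeric(nv - n))
  sol <- ipm_solve(q, cvec, asm$A_eq, asm$b_eq, A_in, b_in, asm$lb, asm$ub,
                   x0 = c(pmin(pmax(problem$d, l), u),
                          rep(NA_real_, nv - n)))
  if (sol$status != "optimal") {
    stop("solve_restricted: solver did not converge (status ", sol$status,
         "); if the budget was chosen manually, certify feasibility with ",
         "min_tae() first")
  }
  w <- sol$x[seq_len(n)]
  err <- as.vector(Matrix::crossprod(problem$X, w)) - problem$t_x
  achieved <- sum((problem$r * abs(err))[!problem$exact])
  if (achieved > tae_budget + 1e-6 * max(1, tae_budget) + tol) {
    stop("solve_restricted: returned point violates the error budget (",
         format(achieved), " > ", format(tae_budget), "); run min_tae() ",
         "and pass a certified budget")
  }
  if (any(abs(err[problem$exact]) > tol * 10)) {
    stop("solve_restricted: exact benchmark constraints not met; the ",
         "problem is infeasible as posed - run min_tae() first")
  }
  structure(list(
    w = w,
    distance = chi_square_distance(w, problem$d),
    per_constraint_error = err,
    achieved_tae = achieved,
    tae_budget_used = tae_budget,
    applied_l = l, applied_u = u,
    modification = list(branch = "direct"),
    status = sol$status,
    objective_certificate = sol$gap),
    class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result> n =", length(x$w),
      " distance =", format(x$distance),
      " achieved TAE =", format(x$achieved_tae),
      " (budget", format(x$tae_budget_used), ")\n")
  cat("  branch:", x$modification$branch, " status:", x$status, "\n")
  invisible(x)
}

## Budget inflation guard against LP/QP round-off mismatch: the LP optimum
## is certified only to the solver's relative gap, so the l1 ball handed to
## the QP is widened a hair beyond it to keep a nonempty interior.
.inflate <- function(budget) budget * (1 + 1e-6) + 1e-9

#' Always-convergent calibration with minimum benchmark error
#'
#' Two-step driver: first the minimum total absolute benchmark error
#' compatible with the range restrictions (TAE*) is certified by linear
#' programming; then the chi-square calibration problem is solved with
#' exactly that error budget (zero when the problem is feasible). A result
#' is returned for every structurally valid problem — incompatible exact
#' constraints are the only failure mode.
#'
#' @param problem a [calibration_problem()].
#' @return A `calibration_result` whose `modification` records TAE* and the
#'   branch taken (`"feasible"` or `"min_tae"`).
#' @examples
#' res <- go_calibrate(intro_example(u = 20))
#' res$modification$tae_star  # 16
#' range(res$w)               # all weights at 20
#' @export
go_calibrate <- function(problem) {
  fe <- min_tae(problem)
  if (identical(fe$status, "infeasible_exact_constraints")) {
    stop("go_calibrate: the exact benchmark constraints are incompatible ",
         "with the range restrictions (minimum exact-subset error ",
         format(fe$exact_error), "); relax the bounds or the exact flags")
  }
  feasible <- isTRUE(fe$feasible)
  budget <- if (feasible) 0 else .inflate(fe$tae_star)
  res <- solve_restricted(problem, budget)
  res$modification <- list(
    branch = if (feasible) "feasible" else "min_tae",
    tae_star = fe$tae_star,
    feasibility = fe)
  res
}

#' Always-convergent calibration with bounded error and minimal bound change
#'
#' Extends [go_calibrate()] with a user budget `eps` for the benchmark error
#' and outer limiting bounds `[L, U]` inside which the range restrictions
#' may be relaxed. Three branches:
#' \describe{
#'   \item{`eps >= TAE*`}{no relaxation needed; identical to
#'     [go_calibrate()] (`eps = Inf` reduces exactly to it).}
#'   \item{`TAE** <= eps < TAE*`}{the minimum total absolute bound change
#'     TAC* is computed by [min_tac()], the relaxed bounds are fixed, and
#'     calibration runs with budget `eps`.}
#'   \item{`eps < TAE**`}{the request is unattainable even at the limiting
#'     bounds; `eps` is replaced by TAE** (recorded in the result) and the
#'     previous branch is applied.}
#' }
#'
#' @inheritParams go_calibrate
#' @param eps nonnegative benchmark-error tolerance (same units as `t_x`);
#'   `Inf` reproduces [go_calibrate()].
#' @param uniform,fix_lower passed to [min_tac()].
#' @return A `calibration_result`; `modification` records TAE*, TAE**, TAC*,
#'   the per-unit relaxations and the branch taken.
#' @examples
#' pr <- intro_example(u = 20, U = 40)
#' res <- go_calibrate_relaxed(pr, eps = 0)
#' res$modification$tac_star  # 16
#' sum(res$w)                 # 2016
#' @export
go_calibrate_relaxed <- function(problem, eps, uniform = FALSE,
                                 fix_lower = FALSE) {
  stopifnot(is.numeric(eps), length(eps) == 1L, eps >= 0)
  tol <- .feastol(problem)
  fe <- min_tae(problem)
  if (identical(fe$status, "infeasible_exact_constraints")) {
    ## the exact subset may still fit inside the limiting box
    lim_pre <- .exact_precheck(problem, problem$L, problem$U)
    if (!lim_pre$ok) {
      stop("go_calibrate_relaxed: exact benchmark constraints are ",
           "incompatible even with the limiting bounds [L, U]")
    }
  } else if (eps >= fe$tae_star - tol) {
    res <- solve_restricted(problem, if (isTRUE(fe$feasible)) 0 else
      .inflate(fe$tae_star))
    res$modification <- list(
      branch = "no_rr_change", eps_requested = eps, eps_used = eps,
      tae_star = fe$tae_star, tac_star = 0, feasibility = fe)
    return(res)
  }
  lim <- min_tae_at_limits(problem)
  if (identical(lim$status, "infeasible_exact_constraints")) {
    stop("go_calibrate_relaxed: exact benchmark constraints are ",
         "incompatible even with the limiting bounds [L, U]")
  }
  substituted <- eps < lim$tae_star - tol
  eps_used <- if (substituted) lim$tae_star else eps
  rel <- min_tac(problem, .inflate(eps_used), uniform = uniform,
                 fix_lower = fix_lower)
  if (!is.null(rel$status) && rel$status == "eps_below_TAE_star_limit") {
    stop("go_calibrate_relaxed: internal branch error; eps below TAE**")
  }
  res <- solve_restricted(problem, .inflate(eps_used),
                          bounds_override = list(l = rel$new_l,
                                                 u = rel$new_u))
  res$modification <- list(
    branch = if (substituted) "eps_substituted_tae_limit" else "min_tac",
    eps_requested = eps, eps_used = eps_used,
    tae_star = fe$tae_star, tae_star_limit = rel$tae_star_limit,
    tac_star = rel$tac_star, lam = rel$lam, mu = rel$mu,
    relaxation = rel)
  res
}
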
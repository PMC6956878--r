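## Linear-programming layer: feasibility certificates, minimum total absolute
## error in benchmark constraints (TAE*, TAE**), and minimum total absolute
## change in range restrictions (TAC*).

## scale-free zero tolerance shared by all feasibility decisions
.feastol <- function(problem) 1e-8 * max(1, sum(abs(problem$t_x)))

## Assemble the benchmark-error rows shared by every solve.
##
## Variables are laid out as (w[1..n], eps[...], alpha, beta) where eps has
## one entry per non-exact constraint in "l1" mode and a single shared entry
## in "linf" mode, and the two Gelman scalars are present only when a ratio
## bound kappa_gb is set.  Exact constraints become equality rows without
## error variables.  Returns the pieces ipm_solve() needs plus index maps.
.assemble <- function(problem, l, u, exact_override = NULL) {
  n <- problem$n
  X <- problem$X
  t_x <- problem$t_x
  exact <- if (is.null(exact_override)) problem$exact else exact_override
  inx <- which(!exact)
  ex <- which(exact)
  linf <- problem$norm == "linf"
  n_eps <- if (linf) min(1L, length(inx)) else length(inx)
  gel <- !is.null(problem$kappa_gb)
  n_gel <- if (gel) 2L else 0L
  nv <- n + n_eps + n_gel
  i_eps <- if (n_eps) n + seq_len(n_eps) else integer(0)
  i_ab <- if (gel) n + n_eps + 1:2 else integer(0)

  Xt <- Matrix::t(X)
  A_eq <- NULL; b_eq <- NULL
  if (length(ex)) {
    A_eq <- cbind(Xt[ex, , drop = FALSE],
                  .zero_mat(length(ex), n_eps + n_gel))
    b_eq <- t_x[ex]
  }
  A_in <- NULL; b_in <- NULL
  if (length(inx)) {
    E <- if (linf) {
      Matrix::Matrix(1, length(inx), 1L, sparse = TRUE)
    } else {
      Matrix::Diagonal(length(inx))
    }
    Xi <- Xt[inx, , drop = FALSE]
    A_in <- rbind(
      cbind(Xi, -E, .zero_mat(length(inx), n_gel)),
      cbind(-Xi, -E, .zero_mat(length(inx), n_gel))
    )
    b_in <- c(t_x[inx], -t_x[inx])
  }
  if (gel) {
    ## alpha * 1 <= w <= beta * 1  and  beta <= kappa * alpha
    Ig <- Matrix::Diagonal(n)
    A_gel <- rbind(
      cbind(Ig, .zero_mat(n, n_eps),
            .zero_mat(n, 1L), Matrix::Matrix(-1, n, 1L)),   # w - beta <= 0
      cbind(-Ig, .zero_mat(n, n_eps),
            Matrix::Matrix(1, n, 1L), .zero_mat(n, 1L)),    # alpha - w <= 0
      cbind(.zero_mat(1L, n + n_eps),
            Matrix::Matrix(-problem$kappa_gb, 1L, 1L), Matrix::Matrix(1, 1L, 1L))
    )
    A_in <- rbind(A_in, A_gel)
    b_in <- c(b_in, numeric(2L * n + 1L))
  }
  lb <- c(l, numeric(n_eps), numeric(n_gel))
  ub <- c(u, rep(Inf, n_eps), rep(Inf, n_gel))
  if (!linf && n_eps) {
    cap <- problem$eps_cap[inx]
    ub[i_eps][!is.na(cap)] <- cap[!is.na(cap)]
  }
  list(nv = nv, i_w = seq_len(n), i_eps = i_eps, i_ab = i_ab,
       inx = inx, ex = ex, linf = linf,
       A_eq = A_eq, b_eq = b_eq, A_in = A_in, b_in = b_in,
       lb = lb, ub = ub)
}

.zero_mat <- function(nr, nc) {
  Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                       dims = c(nr, nc))
}

## Feasibility pre-check for the "hard" constraints inside a box: exact
## constraints (error cap 0) and error-capped constraints. Solves the
## always-feasible LP minimising the total overshoot beyond the caps; a
## positive optimum certifies that no weight vector in the box can satisfy
## the hard constraints, whatever the other errors.
.exact_precheck <- function(problem, l, u) {
  cap <- ifelse(problem$exact, 0,
                ifelse(is.na(problem$eps_cap), Inf, problem$eps_cap))
  hd <- which(is.finite(cap))
  if (!length(hd)) return(list(ok = TRUE, err = 0))
  n <- problem$n
  k <- length(hd)
  Xh <- Matrix::t(problem$X[, hd, drop = FALSE])
  Ik <- Matrix::Diagonal(k)
  A_in <- rbind(cbind(Xh, -Ik), cbind(-Xh, -Ik))
  b_in <- c(problem$t_x[hd] + cap[hd], -problem$t_x[hd] + cap[hd])
  sol <- ipm_solve(numeric(n + k), c(numeric(n), rep(1, k)),
                   A_in = A_in, b_in = b_in,
                   lb = c(l, numeric(k)), ub = c(u, rep(Inf, k)))
  tol <- .feastol(problem)
  list(ok = sol$status == "optimal" && sol$obj <= tol, err = sol$obj)
}

#' Minimum total absolute error in benchmark constraints (TAE*)
#'
#' Solves, by linear programming, for the smallest total absolute error that
#' must be tolerated in the (non-exact) benchmark constraints for them to be
#' compatible with the range restrictions `l <= w <= u`:
#' `TAE* = min ||X'w - t_x||_1` over the box, with per-constraint weights
#' `r` in the l1 objective. Exact constraints are imposed as equality rows
#' (no error variable); `"linf"` norm mode replaces the error vector by a
#' single scalar shared across non-exact constraints. A Gelman ratio bound,
#' if set on the problem, is added as linear constraints.
#'
#' `TAE* = 0` (within a scale-free tolerance) certifies that the
#' range-restricted calibration problem is feasible.
#'
#' @param problem a [calibration_problem()].
#' @return An object of class `feasibility_report`: `feasible`, `tae_star`,
#'   per-constraint errors `eps_tilde`, a witness weight vector `witness_w`
#'   attaining the optimum, solver `status` and the solver's
#'   `objective_certificate` (complementarity gap).
#' @examples
#' min_tae(intro_example(u = 20))$tae_star   # 16
#' @export
min_tae <- function(problem) {
  .min_tae_box(problem, problem$l, problem$u)
}

#' Minimum benchmark error at the limiting bounds (TAE**)
#'
#' Identical to [min_tae()] but with the range restrictions replaced by the
#' outer limiting bounds `L <= w <= U`: the smallest benchmark error that
#' remains necessary even after relaxing the bounds as far as allowed.
#' Always `TAE** <= TAE*`.
#'
#' @inheritParams min_tae
#' @return A `feasibility_report` (see [min_tae()]).
#' @export
min_tae_at_limits <- function(problem) {
  .min_tae_box(problem, problem$L, problem$U)
}

.min_tae_box <- function(problem, l, u) {
  if (any(is.finite(l) & is.finite(u) & l > u)) {
    stop("min_tae: lower bound above upper bound; fix the range restrictions")
  }
  n <- problem$n
  pre <- .exact_precheck(problem, l, u)
  if (!pre$ok) {
    return(structure(list(
      feasible = FALSE, tae_star = Inf,
      eps_tilde = rep(NA_real_, problem$p), witness_w = NULL,
      status = "infeasible_exact_constraints",
      objective_certificate = NA_real_, exact_error = pre$err),
      class = "feasibility_report"))
  }
  asm <- .assemble(problem, l, u)
  cvec <- numeric(asm$nv)
  if (length(asm$i_eps)) {
    cvec[asm$i_eps] <- if (asm$linf) 1 else problem$r[asm$inx]
  }
  sol <- ipm_solve(numeric(asm$nv), cvec, asm$A_eq, asm$b_eq,
                   asm$A_in, asm$b_in, asm$lb, asm$ub,
                   x0 = c(pmin(pmax(problem$d, l), u),
                          rep(NA_real_, asm$nv - n)))
  w <- sol$x[asm$i_w]
  err <- abs(as.vector(Matrix::crossprod(problem$X, w)) - problem$t_x)
  eps <- err
  eps[problem$exact] <- 0
  tol <- .feastol(problem)
  structure(list(
    feasible = sol$status == "optimal" && sol$obj <= tol,
    tae_star = max(sol$obj, 0),
    eps_tilde = eps, witness_w = w, status = sol$status,
    objective_certificate = sol$gap),
    class = "feasibility_report")
}

#' @export
print.feasibility_report <- function(x, ...) {
  cat("<feasibility_report>", if (x$feasible) "FEASIBLE" else "infeasible",
      " TAE* =", format(x$tae_star), " status:", x$status, "\n")
  invisible(x)
}

#' Feasibility certificate for a range-restricted calibration problem
#'
#' The benchmark constraints and range restrictions admit a common solution
#' iff the minimum total absolute error is zero; this wraps [min_tae()] and
#' applies the package's scale-free zero tolerance
#' `TAE* <= 1e-8 * max(1, ||t_x||_1)`.
#'
#' @inheritParams min_tae
#' @return list with `feasible` (logical) and `report` (the
#'   `feasibility_report`).
#' @examples
#' assess_feasibility(intro_example())$feasible        # TRUE
#' assess_feasibility(intro_example(u = 20))$feasible  # FALSE
#' @export
assess_feasibility <- function(problem) {
  rep <- min_tae(problem)
  list(feasible = isTRUE(rep$feasible), report = rep)
}

#' Minimum total absolute change in range restrictions (TAC*)
#'
#' Finds the smallest total relaxation of the bounds — lower bounds decreased
#' by `lambda >= 0`, upper bounds increased by `mu >= 0`, always inside the
#' limiting box `[L, U]` — such that the benchmark constraints can be met
#' with total absolute error at most `eps`:
#' `TAC* = min sum(lambda) + sum(mu)`.
#'
#' For `eps >= TAE*` the trivial solution `TAC* = 0` is returned. For
#' `eps < TAE**` (the minimum error achievable even at the limiting bounds)
#' no relaxation can reach the requested error and the report carries status
#' `"eps_below_TAE_star_limit"` together with `TAE**` as the smallest
#' admissible request.
#'
#' @inheritParams min_tae
#' @param eps nonnegative benchmark-error budget (same units as `t_x`).
#' @param uniform logical; if `TRUE` a single scalar change is shared by all
#'   units for each of `lambda` and `mu` (one-parameter mode).
#' @param fix_lower logical; if `TRUE` the lower bounds are kept fixed
#'   (`lambda = 0`), e.g. to preserve positivity `l = 0`.
#' @return An object of class `relaxation_report`: `tac_star`, per-unit
#'   relaxations `lam` and `mu`, the relaxed bounds `new_l`, `new_u`, the
#'   realised benchmark error `achieved_eps`, a witness `witness_w`,
#'   `tae_star`, `tae_star_limit` (TAE**), and `status`.
#' @examples
#' pr <- intro_example(u = 20, U = 40)
#' min_tac(pr, eps = 0)$tac_star   # 16
#' @export
min_tac <- function(problem, eps, uniform = FALSE, fix_lower = FALSE) {
  stopifnot(is.numeric(eps), length(eps) == 1L, eps >= 0)
  l <- problem$l; u <- problem$u; L <- problem$L; U <- problem$U
  if (any(is.finite(L) & is.finite(l) & L > l) ||
      any(is.finite(u) & is.finite(U) & u > U)) {
    stop("min_tac: limiting bounds must satisfy L <= l and u <= U")
  }
  tol <- .feastol(problem)
  base <- min_tae(problem)
  if (identical(base$status, "infeasible_exact_constraints")) {
    lim <- min_tae_at_limits(problem)
    if (identical(lim$status, "infeasible_exact_constraints")) {
      return(structure(list(
        tac_star = NA_real_, lam = NULL, mu = NULL,
        new_l = l, new_u = u, achieved_eps = NA_real_, witness_w = NULL,
        tae_star = Inf, tae_star_limit = Inf,
        status = "infeasible_exact_constraints"),
        class = "relaxation_report"))
    }
  }
  n <- problem$n
  if (is.finite(base$tae_star) && eps >= base$tae_star - tol) {
    return(structure(list(
      tac_star = 0, lam = numeric(n), mu = numeric(n),
      new_l = l, new_u = u,
      achieved_eps = base$tae_star, witness_w = base$witness_w,
      tae_star = base$tae_star, tae_star_limit = NA_real_,
      status = "trivial_no_change"),
      class = "relaxation_report"))
  }
  lim <- min_tae_at_limits(problem)
  if (!is.finite(lim$tae_star) || eps < lim$tae_star - tol) {
    return(structure(list(
      tac_star = NA_real_, lam = NULL, mu = NULL,
      new_l = l, new_u = u, achieved_eps = NA_real_, witness_w = NULL,
      tae_star = base$tae_star, tae_star_limit = lim$tae_star,
      status = "eps_below_TAE_star_limit"),
      class = "relaxation_report"))
  }

  ## units whose bounds can actually move
  i_lam <- if (fix_lower) integer(0) else
    which(is.finite(l) & (l - L) > 0)
  i_mu <- which(is.finite(u) & (U - u) > 0)
  n_lam <- if (uniform) min(1L, length(i_lam)) else length(i_lam)
  n_mu <- if (uniform) min(1L, length(i_mu)) else length(i_mu)

  asm <- .assemble(problem, L, U)   # w bounded by the limiting box
  nv <- asm$nv + n_lam + n_mu
  j_lam <- if (n_lam) asm$nv + seq_len(n_lam) else integer(0)
  j_mu <- if (n_mu) asm$nv + n_lam + seq_len(n_mu) else integer(0)
  pad <- function(A) if (is.null(A)) NULL else
    cbind(A, .zero_mat(nrow(A), n_lam + n_mu))
  A_eq <- pad(asm$A_eq); b_eq <- asm$b_eq
  A_in <- pad(asm$A_in); b_in <- asm$b_in
  ## error budget: r' eps <= eps (single eps variable already in linf mode)
  if (length(asm$i_eps)) {
    row <- numeric(nv)
    row[asm$i_eps] <- if (asm$linf) 1 else problem$r[asm$inx]
    A_in <- rbind(A_in, Matrix::Matrix(row, 1L, nv, sparse = TRUE))
    b_in <- c(b_in, eps)
  }
  ## -w_i - lambda_(i) <= -l_i  and  w_i - mu_(i) <= u_i; finite bounds that
  ## cannot move (and are not already implied by the limiting box) stay hard
  if (length(i_lam)) {
    A_lam <- .zero_mat(length(i_lam), nv)
    A_lam[, i_lam] <- -Matrix::Diagonal(length(i_lam))
    A_lam[, j_lam] <- -.incidence(length(i_lam), n_lam, uniform)
    A_in <- rbind(A_in, A_lam); b_in <- c(b_in, -l[i_lam])
  }
  hard_l <- setdiff(which(is.finite(l) & !(is.finite(L) & L >= l)), i_lam)
  if (length(hard_l)) {
    A_h <- .zero_mat(length(hard_l), nv)
    A_h[, hard_l] <- -Matrix::Diagonal(length(hard_l))
    A_in <- rbind(A_in, A_h); b_in <- c(b_in, -l[hard_l])
  }
  if (length(i_mu)) {
    A_mu <- .zero_mat(length(i_mu), nv)
    A_mu[, i_mu] <- Matrix::Diagonal(length(i_mu))
    A_mu[, j_mu] <- -.incidence(length(i_mu), n_mu, uniform)
    A_in <- rbind(A_in, A_mu); b_in <- c(b_in, u[i_mu])
  }
  hard_u <- setdiff(which(is.finite(u) & !(is.finite(U) & U <= u)), i_mu)
  if (length(hard_u)) {
    A_h <- .zero_mat(length(hard_u), nv)
    A_h[, hard_u] <- Matrix::Diagonal(length(hard_u))
    A_in <- rbind(A_in, A_h); b_in <- c(b_in, u[hard_u])
  }

  lb <- c(asm$lb, numeric(n_lam + n_mu))
  ub <- c(asm$ub,
          if (n_lam) {
            if (uniform) min(l[i_lam] - L[i_lam]) else l[i_lam] - L[i_lam]
          },
          if (n_mu) {
            if (uniform) min(U[i_mu] - u[i_mu]) else U[i_mu] - u[i_mu]
          })
  cvec <- numeric(nv)
  if (n_lam) cvec[j_lam] <- if (uniform) length(i_lam) else 1
  if (n_mu) cvec[j_mu] <- if (uniform) length(i_mu) else 1

  sol <- ipm_solve(numeric(nv), cvec, A_eq, b_eq, A_in, b_in, lb, ub)
  w <- sol$x[asm$i_w]
  lam <- numeric(n); mu <- numeric(n)
  if (n_lam) lam[i_lam] <- if (uniform) sol$x[j_lam] else sol$x[j_lam]
  if (n_mu) mu[i_mu] <- if (uniform) sol$x[j_mu] else sol$x[j_mu]
  lam <- pmax(0, pmin(lam, ifelse(is.finite(l), l - L, 0)))
  mu <- pmax(0, pmin(mu, ifelse(is.finite(u), U - u, 0)))
  errs <- abs(as.vector(Matrix::crossprod(problem$X, w)) - problem$t_x)
  achieved <- sum((problem$r * errs)[!problem$exact])
  structure(list(
    tac_star = sum(lam) + sum(mu), lam = lam, mu = mu,
    new_l = l - lam, new_u = u + mu,
    achieved_eps = achieved, witness_w = w,
    tae_star = base$tae_star, tae_star_limit = lim$tae_star,
    status = sol$status, uniform = uniform,
    objective_certificate = sol$gap),
    class = "relaxation_report")
}

## unit-to-parameter incidence: identity, or a ones column in uniform mode
.incidence <- function(n_units, n_par, uniform) {
  if (uniform) Matrix::Matrix(1, n_units, 1L, sparse = TRUE)
  else Matrix::Diagonal(n_units)
}

#' @export
print.relaxation_report <- function(x, ...) {
  cat("<relaxation_report> TAC* =", format(x$tac_star),
      " status:", x$status, "\n")
  if (!is.null(x$tae_star)) {
    cat("  TAE* =", format(x$tae_star),
        if (!is.null(x$tae_star_limit) && !is.na(x$tae_star_limit))
          paste(" TAE** =", format(x$tae_star_limit)), "\n")
  }
  invisible(x)
}
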
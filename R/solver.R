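#' @importFrom methods as new
#' @importFrom Matrix Matrix sparseMatrix Diagonal crossprod t forceSymmetric
NULL

## Internal convex solver.
##
## Minimises 0.5 * sum(q * x^2) + sum(cvec * x) subject to
##   A_eq x  = b_eq
##   A_in x <= b_in
##   lb <= x <= ub   (components may be -Inf / +Inf)
## with q >= 0 componentwise (q = 0 everywhere gives a linear program).
##
## A single primal-dual interior-point method (Mehrotra predictor-corrector,
## infeasible start) covers every optimisation problem in the package: the
## feasibility linear programs and the chi-square calibration quadratic
## program, whose Hessian is diagonal.  Constraints are kept sparse; each
## iteration factorises the (m x m) normal-equations matrix A' Theta^-1 A
## with a sparse Cholesky from the Matrix package.
##
## The caller must supply a feasible, bounded problem; the package arranges
## this by construction (see min_tae(), min_tac()).  Non-convergence within
## maxit is reported through status = "max_iterations".

ipm_solve <- function(q, cvec, A_eq = NULL, b_eq = NULL, A_in = NULL,
                      b_in = NULL, lb, ub, x0 = NULL, tol = 1e-9,
                      maxit = 200L) {
  nx <- length(cvec)
  stopifnot(length(q) == nx, length(lb) == nx, length(ub) == nx, all(q >= 0))
  if (any(ub < lb)) stop("ipm_solve: some upper bound below lower bound")

  A_eq <- .as_sparse(A_eq, nx)
  A_in <- .as_sparse(A_in, nx)
  me <- if (is.null(A_eq)) 0L else nrow(A_eq)
  mi <- if (is.null(A_in)) 0L else nrow(A_in)
  if (is.null(b_eq)) b_eq <- numeric(0)
  if (is.null(b_in)) b_in <- numeric(0)
  stopifnot(length(b_eq) == me, length(b_in) == mi)

  ## presolve: variables fixed by equal bounds are substituted out
  fx <- is.finite(lb) & is.finite(ub) & (ub - lb) <= 1e-12 * pmax(1, abs(lb))
  if (any(fx)) {
    xfix <- lb
    keep <- which(!fx)
    const_obj <- sum(0.5 * q[fx] * lb[fx]^2 + cvec[fx] * lb[fx])
    if (me) b_eq <- b_eq - as.vector(A_eq[, fx, drop = FALSE] %*% lb[fx])
    if (mi) b_in <- b_in - as.vector(A_in[, fx, drop = FALSE] %*% lb[fx])
    sub <- ipm_solve(q[keep], cvec[keep],
                     if (me) A_eq[, keep, drop = FALSE], b_eq,
                     if (mi) A_in[, keep, drop = FALSE], b_in,
                     lb[keep], ub[keep],
                     x0 = if (!is.null(x0)) x0[keep], tol = tol, maxit = maxit)
    xfix[keep] <- sub$x
    sub$x <- xfix
    sub$obj <- sub$obj + const_obj
    return(sub)
  }

  lb_entry <- lb; ub_entry <- ub; q_entry <- q; c_entry <- cvec

  ## drop linearly dependent equality rows (e.g. two partitions of the same
  ## population imposed exactly); consistency of the dropped rows is the
  ## caller's pre-checked responsibility
  if (me > 1L) {
    QR <- qr(as.matrix(Matrix::t(A_eq)))
    if (QR$rank < me) {
      keep_r <- sort(QR$pivot[seq_len(QR$rank)])
      A_eq <- A_eq[keep_r, , drop = FALSE]
      b_eq <- b_eq[keep_r]
      me <- length(keep_r)
    }
  }

  ## split free linear variables (q = 0, no finite bound) as x = x+ - x-
  free <- !is.finite(lb) & !is.finite(ub) & q == 0
  nfree <- sum(free)
  if (nfree) {
    jf <- which(free)
    q <- c(q, numeric(nfree))
    cvec <- c(cvec, -cvec[jf])      # negative part gets the opposite cost
    lb[jf] <- 0; lb <- c(lb, numeric(nfree))
    ub <- c(ub, rep(Inf, nfree))
    if (me) A_eq <- cbind(A_eq, -A_eq[, jf, drop = FALSE])
    if (mi) A_in <- cbind(A_in, -A_in[, jf, drop = FALSE])
    if (!is.null(x0)) {
      negpart <- pmax(-x0[jf], 0)
      x0[jf] <- pmax(x0[jf], 0)
      x0 <- c(x0, negpart)
    }
  }
  nv0 <- length(cvec)

  ## slacks on inequality rows -> all rows become equalities
  if (mi) {
    q <- c(q, numeric(mi)); cvec <- c(cvec, numeric(mi))
    lb <- c(lb, numeric(mi)); ub <- c(ub, rep(Inf, mi))
  }
  nv <- length(cvec)
  A <- rbind(
    if (me) cbind(A_eq, .as_sparse(NULL, 0L, me, mi)),
    if (mi) cbind(A_in, Diagonal(mi))
  )
  if (is.null(A)) {
    x <- .box_minimise(q, cvec, lb, ub, x0)
    x <- .unsplit(x, nfree, free, nv0)[seq_len(nx)]
    x <- pmin(pmax(x, lb_entry), ub_entry)
    return(list(x = x, obj = sum(0.5 * q_entry * x^2 + c_entry * x),
                status = "optimal", iterations = 0L, gap = 0,
                primal_inf = 0, dual_inf = 0))
  }
  A <- as(A, "CsparseMatrix")
  b <- c(b_eq, b_in)
  m <- nrow(A)

  hasL <- is.finite(lb); hasU <- is.finite(ub)
  ncomp <- sum(hasL) + sum(hasU)

  ## interior starting point
  v <- numeric(nv)
  both <- hasL & hasU
  v[both] <- (lb[both] + ub[both]) / 2
  lo <- hasL & !hasU; v[lo] <- lb[lo] + 1 + 0.1 * abs(lb[lo])
  hi <- hasU & !hasL; v[hi] <- ub[hi] - 1 - 0.1 * abs(ub[hi])
  if (!is.null(x0)) {
    x0 <- c(x0, rep(NA_real_, nv - length(x0)))
    ok <- !is.na(x0)
    marg <- ifelse(both, 0.05 * (ub - lb), 0.1 * (1 + abs(v)))
    v[ok] <- pmin(pmax(x0[ok], (lb + marg)[ok]), (ub - marg)[ok])
  }
  if (mi) { # slack start from the inequality residuals
    sl <- b_in - as.vector(A_in %*% v[seq_len(nv0)])
    v[nv0 + seq_len(mi)] <- pmax(sl, 1 + 0.01 * abs(b_in))
  }
  z <- ifelse(hasL, 1 + 0.1 * abs(cvec), 0)
  tt <- ifelse(hasU, 1 + 0.1 * abs(cvec), 0)
  y <- numeric(m)

  bscale <- 1 + max(abs(b))
  cscale <- 1 + max(abs(cvec))
  delta_p <- 1e-11
  delta_d <- 1e-11 * bscale
  status <- "max_iterations"
  it_done <- maxit
  gap <- Inf; pinf <- Inf; dinf <- Inf
  best <- list(score = Inf)

  for (it in seq_len(maxit)) {
    ## strictly interior gaps; the floor keeps round-off from producing 0/0
    g <- ifelse(hasL, pmax(v - lb, 1e-300), Inf)
    h <- ifelse(hasU, pmax(ub - v, 1e-300), Inf)
    rp <- as.vector(A %*% v) - b
    rd <- q * v + cvec - as.vector(crossprod(A, y)) - z + tt
    mu <- if (ncomp) (sum(z[hasL] * g[hasL]) + sum(tt[hasU] * h[hasU])) / ncomp else 0
    pobj <- sum(0.5 * q * v^2 + cvec * v)
    gap <- mu * max(ncomp, 1)
    pinf <- max(abs(rp)) / bscale
    dinf <- max(abs(rd)) / cscale
    gaprel <- gap / (1 + abs(pobj))
    ## remember the most accurate iterate: near-degenerate optima can drift
    ## once complementarity is exhausted
    score <- max(pinf, dinf, gaprel)
    if (score < best$score) {
      best <- list(score = score, v = v, pinf = pinf, dinf = dinf,
                   gaprel = gaprel, it = it)
    }
    if (pinf <= tol && dinf <= tol && gaprel <= 50 * tol) {
      status <- "optimal"; it_done <- it - 1L
      break
    }
    ## complementarity exhausted: no further progress is possible
    if (ncomp && mu <= 1e-14 * (1 + abs(pobj))) {
      status <- "stalled"; it_done <- it - 1L
      break
    }

    theta <- q + ifelse(hasL, z / g, 0) + ifelse(hasU, tt / h, 0) + delta_p
    ith <- 1 / theta
    ch <- NULL
    repeat {
      M <- forceSymmetric(A %*% Diagonal(x = ith) %*% Matrix::t(A)) +
        Diagonal(m, delta_d)
      warned <- FALSE
      ch <- withCallingHandlers(
        tryCatch(Matrix::Cholesky(M, LDL = TRUE), error = function(e) NULL),
        warning = function(w) {
          warned <<- TRUE
          invokeRestart("muffleWarning")
        })
      if (!is.null(ch) && (!warned || delta_d >= 1e-8 * bscale)) break
      delta_d <- delta_d * 100
      if (delta_d > 1e2 * bscale) stop("ipm_solve: normal equations singular")
    }
    newton <- function(compl_l, compl_u) {
      rhat <- rd + ifelse(hasL, compl_l / g, 0) - ifelse(hasU, compl_u / h, 0)
      rhs <- as.vector(A %*% (rhat * ith)) - rp
      dy <- as.vector(Matrix::solve(ch, rhs))
      dv <- (as.vector(crossprod(A, dy)) - rhat) * ith
      dz <- ifelse(hasL, -(z * dv + compl_l) / g, 0)
      dt <- ifelse(hasU, (tt * dv - compl_u) / h, 0)
      list(dv = dv, dy = dy, dz = dz, dt = dt)
    }
    ## predictor (affine scaling direction)
    aff <- newton(ifelse(hasL, g * z, 0), ifelse(hasU, h * tt, 0))
    ap_a <- min(1, .maxstep_down(g, aff$dv, hasL), .maxstep_up(h, aff$dv, hasU))
    ad_a <- min(1, .maxstep_down(z, aff$dz, hasL), .maxstep_down(tt, aff$dt, hasU))
    if (ncomp) {
      mu_aff <- (sum((g + ap_a * aff$dv)[hasL] * (z + ad_a * aff$dz)[hasL]) +
                 sum((h - ap_a * aff$dv)[hasU] * (tt + ad_a * aff$dt)[hasU])) /
        ncomp
      sigma <- min(1, max(0, (mu_aff / mu))^3)
      if (!is.finite(sigma)) sigma <- 0
      ## corrector with second-order terms
      cl <- ifelse(hasL, g * z + aff$dv * aff$dz - sigma * mu, 0)
      cu <- ifelse(hasU, h * tt - aff$dv * aff$dt - sigma * mu, 0)
      st <- newton(cl, cu)
    } else st <- aff

    if (!all(is.finite(st$dv)) || !all(is.finite(st$dy))) {
      status <- "numerical_failure"; it_done <- it
      break
    }
    tau <- 0.9995
    ap <- tau * min(1 / tau, .maxstep_down(g, st$dv, hasL),
                    .maxstep_up(h, st$dv, hasU))
    ad <- tau * min(1 / tau, .maxstep_down(z, st$dz, hasL),
                    .maxstep_down(tt, st$dt, hasU))
    v <- v + ap * st$dv
    y <- y + ad * st$dy
    z <- z + ad * st$dz
    tt <- tt + ad * st$dt
  }

  ## on an imperfect exit, fall back to the best iterate seen and accept it
  ## when its certificates are within a small multiple of the target
  if (status != "optimal" && is.finite(best$score)) {
    v <- best$v
    pinf <- best$pinf; dinf <- best$dinf
    gap <- best$gaprel * (1 + abs(sum(0.5 * q * v^2 + cvec * v)))
    if (pinf <= 1e3 * tol && dinf <= 1e3 * tol && best$gaprel <= 1e4 * tol) {
      status <- "optimal"
    }
  }
  x <- .unsplit(v[seq_len(nv0)], nfree, free, nv0)[seq_len(nx)]
  x <- pmin(pmax(x, lb_entry), ub_entry)
  obj <- sum(0.5 * q_entry * x^2 + c_entry * x)
  list(x = x, obj = obj, status = status, iterations = it_done,
       gap = gap, primal_inf = pinf, dual_inf = dinf, y = y)
}

.as_sparse <- function(A, nx, nr = NULL, nc = NULL) {
  if (is.null(A)) {
    if (is.null(nr)) return(NULL)
    return(sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                        dims = c(nr, nc)))
  }
  A <- as(as(Matrix(A, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  stopifnot(ncol(A) == nx)
  A
}

## largest alpha with p + alpha * dp >= 0 restricted to active components
.maxstep_down <- function(p, dp, act) {
  i <- act & dp < 0
  if (!any(i)) return(Inf)
  min(-p[i] / dp[i])
}
## largest alpha with p - alpha * dp >= 0 (upper-bound gaps shrink when dv > 0)
.maxstep_up <- function(p, dv, act) {
  i <- act & dv > 0
  if (!any(i)) return(Inf)
  min(p[i] / dv[i])
}

.unsplit <- function(v, nfree, free, nv0) {
  if (!nfree) return(v)
  n_orig <- nv0 - nfree
  x <- v[seq_len(n_orig)]
  x[which(free)] <- x[which(free)] - v[n_orig + seq_len(nfree)]
  x
}

## separable box minimiser for the degenerate no-constraint case
.box_minimise <- function(q, cvec, lb, ub, x0) {
  x <- numeric(length(cvec))
  pos <- q > 0
  x[pos] <- pmin(pmax(-cvec[pos] / q[pos], lb[pos]), ub[pos])
  lin <- !pos
  x[lin] <- ifelse(cvec[lin] > 0, lb[lin],
                   ifelse(cvec[lin] < 0, ub[lin],
                          pmin(pmax(0, lb[lin]), ub[lin])))
  if (any(!is.finite(x))) stop("unbounded problem in box minimisation")
  x
}
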
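# Independent oracles and random-instance builders used across the suite.
# The oracles are deliberately naive (exhaustive grids, closed forms) and
# share no code with the package's interior-point solver.

# all grid points of [l, u]^n with m points per axis, as an m^n x n matrix
grid_points <- function(l, u, m) {
  n <- length(l)
  axes <- lapply(seq_len(n), function(i) seq(l[i], u[i], length.out = m))
  as.matrix(do.call(expand.grid, c(axes, KEEP.OUT.ATTRS = FALSE)))
}

# exhaustive-search minimum weighted total absolute error over the grid
brute_tae <- function(X, t_x, r, l, u, m) {
  W <- grid_points(l, u, m)
  E <- abs(W %*% X - matrix(t_x, nrow(W), length(t_x), byrow = TRUE))
  min(as.vector(E %*% r))
}

# exhaustive minimax error over the grid
brute_tae_linf <- function(X, t_x, l, u, m) {
  W <- grid_points(l, u, m)
  E <- abs(W %*% X - matrix(t_x, nrow(W), length(t_x), byrow = TRUE))
  min(apply(E, 1L, max))
}

# Lipschitz constant of w -> sum_j r_j |x_j'w - t_j| w.r.t. the sup norm,
# used to convert grid resolution into an objective tolerance
tae_lipschitz <- function(X, r) sum(abs(X) %*% r)

# random small calibration problem over continuous variables; bounds and
# data are integer-valued so grid oracles line up with vertices
random_tiny_problem <- function(n, p, seed) {
  set.seed(seed)
  X <- matrix(sample(0:2, n * p, replace = TRUE), n, p)
  while (any(colSums(abs(X)) == 0)) {
    X <- matrix(sample(0:2, n * p, replace = TRUE), n, p)
  }
  d <- sample(1:4, n, replace = TRUE)
  l <- rep(0, n)
  u <- sample(2:4, n, replace = TRUE)
  t_x <- as.vector(crossprod(X, round(runif(n, 0, 6))))
  list(X = X, d = d, l = l, u = u, t_x = t_x, r = rep(1, p))
}

# wrap plain matrices into the package's problem object
as_problem <- function(X, d, t_x, l = 0, u = Inf, L = NULL, U = NULL,
                       exact = FALSE, r = 1, norm = "l1", kappa_gb = NULL) {
  n <- nrow(X)
  df <- data.frame(unit_id = seq_len(n), weight = d)
  for (j in seq_len(ncol(X))) df[[paste0("x", j)]] <- X[, j]
  bm <- benchmark_spec(paste0("x", seq_len(ncol(X))), NA_character_,
                       t_x, exact = exact, r = r)
  calibration_problem(sample_data(df), bm,
                      range_restrictions(l = l, u = u, L = L, U = U),
                      norm = norm, kappa_gb = kappa_gb)
}

# small categorical survey used by several IO / design-matrix tests
toy_survey <- function() {
  sample_data(data.frame(
    unit_id = 1:6,
    psu_id = c("a", "a", "b", "b", "c", "c"),
    weight = c(2, 2, 3, 3, 1, 1),
    gender = c("F", "F", "M", "M", "F", "M"),
    age = c(10, 20, 30, 40, 50, 60)
  ))
}
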
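#' Survey microdata container
#'
#' Bundles one row per sampled unit with its identifier, optional primary
#' sampling unit (PSU), the survey variables available for benchmarking, and
#' the initial (design) weights `d`.
#'
#' @param data data.frame of survey variables (categorical columns as factor
#'   or character, continuous as numeric). Columns named in `id`, `weight`
#'   and `psu` are removed from the variable set.
#' @param id name of the unit identifier column (values must be unique).
#' @param weight name of the initial-weight column (all values must be > 0).
#' @param psu optional name of the PSU identifier column.
#' @return An object of class `sample_data` with elements `variables`
#'   (data.frame), `unit_id`, `psu_id` (or `NULL`), `d` and `n`.
#' @examples
#' s <- sample_data(data.frame(unit_id = 1:3, weight = 2,
#'                             gender = c("F", "F", "M")))
#' s$n
#' @export
sample_data <- function(data, id = "unit_id", weight = "weight", psu = "psu_id") {
  stopifnot(is.data.frame(data))
  if (!id %in% names(data)) stop("sample data: missing id column '", id, "'")
  if (!weight %in% names(data)) {
    stop("sample data: missing weight column '", weight, "'")
  }
  d <- as.numeric(data[[weight]])
  bad <- which(!is.finite(d) | d <= 0)
  if (length(bad)) {
    stop("sample data: non-positive or missing weight in row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  uid <- data[[id]]
  if (anyDuplicated(uid)) stop("sample data: duplicate unit_id values")
  if (nrow(data) < 1L) stop("sample data: need at least one unit")
  psu_id <- if (!is.null(psu) && psu %in% names(data)) data[[psu]] else NULL
  drop <- c(id, weight, if (!is.null(psu)) psu)
  vars <- data[setdiff(names(data), drop)]
  structure(list(variables = vars, unit_id = uid, psu_id = psu_id,
                 d = d, n = nrow(data)),
            class = "sample_data")
}

#' @export
print.sample_data <- function(x, ...) {
  cat("<sample_data> n =", x$n, "units;",
      ncol(x$variables), "variables;",
      if (is.null(x$psu_id)) "no PSU ids" else
        paste(length(unique(x$psu_id)), "PSUs"), "\n")
  cat("  sum(d) =", format(sum(x$d)), "\n")
  invisible(x)
}

## row subset used by the jackknife; optionally rescales weights
.subset_sample <- function(sample, keep, d_scale = 1) {
  out <- sample
  out$variables <- sample$variables[keep, , drop = FALSE]
  out$unit_id <- sample$unit_id[keep]
  if (!is.null(sample$psu_id)) out$psu_id <- sample$psu_id[keep]
  out$d <- sample$d[keep] * d_scale
  out$n <- length(out$d)
  out
}

#' Benchmark constraint table
#'
#' An ordered set of benchmark constraints (BC). Each constraint is either a
#' cell of a (cross-)classification of categorical variables, a continuous
#' variable whose weighted total is benchmarked, or the all-units constraint
#' `"*"` (the weighted sample size). Constraint order is meaningful: every
#' per-constraint output of the package follows it.
#'
#' @param variables character vector; variable names, `";"`-joined for
#'   cross-classifications, or `"*"` for the all-units constraint.
#' @param categories character vector of `";"`-joined category labels
#'   (matched as exact strings after whitespace trimming), `NA` for
#'   continuous or all-units constraints.
#' @param total nonnegative benchmark population totals.
#' @param exact logical; exact constraints admit no error in any feasibility
#'   or calibration solve.
#' @param r nonnegative per-constraint error weights used in the total
#'   absolute error objective (default 1).
#' @param v optional positive normalisation totals (benchmark table totals),
#'   see [apply_normalisation()].
#' @param eps_cap optional per-constraint upper bound on the allowed absolute
#'   error (`NA` = unbounded); ignored for exact constraints.
#' @return An object of class `benchmark_spec` (a data.frame).
#' @examples
#' benchmark_spec(c("gender", "gender"), c("F", "M"), c(51, 49))
#' @export
benchmark_spec <- function(variables, categories = NA_character_, total,
                           exact = FALSE, r = 1, v = NA_real_,
                           eps_cap = NA_real_) {
  p <- length(total)
  if (p < 1L) stop("benchmark spec: need at least one constraint (p >= 1)")
  out <- data.frame(
    variables = trimws(rep_len(as.character(variables), p)),
    categories = trimws(rep_len(as.character(categories), p)),
    total = as.numeric(total),
    exact = rep_len(as.logical(exact), p),
    r = rep_len(as.numeric(r), p),
    v = rep_len(as.numeric(v), p),
    eps_cap = rep_len(as.numeric(eps_cap), p),
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(out$total))) stop("benchmark spec: non-finite totals")
  if (any(out$r < 0, na.rm = TRUE)) {
    stop("benchmark spec: constraint weights r must be nonnegative")
  }
  if (any(!is.na(out$v) & out$v <= 0)) {
    stop("benchmark spec: normalisation totals v must be positive")
  }
  class(out) <- c("benchmark_spec", "data.frame")
  out
}

#' @export
print.benchmark_spec <- function(x, ...) {
  cat("<benchmark_spec>", nrow(x), "constraints (",
      sum(x$exact), "exact )\n")
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("  ...", nrow(x) - 10L, "more\n")
  invisible(x)
}

#' Combine benchmark tables
#'
#' @param ... `benchmark_spec` objects, concatenated in order.
#' @return A single `benchmark_spec`.
#' @export
c.benchmark_spec <- function(...) {
  out <- do.call(rbind, lapply(list(...), as.data.frame))
  class(out) <- c("benchmark_spec", "data.frame")
  rownames(out) <- NULL
  out
}

#' Range restrictions on calibration weights
#'
#' Lower/upper bounds `l <= w <= u` enforced during calibration, and outer
#' limiting bounds `L <= w <= U` inside which the bounds may be relaxed by
#' [min_tac()]. Scalars are recycled per unit; `mode = "relative"` reads all
#' four as multiples of the initial weights `d` and they are expanded to
#' absolute per-unit vectors when the problem is built. Infinite bounds are
#' kept as infinities and dropped from solver constraint sets.
#'
#' @param l,u inner bounds (scalar or per-unit vector; may be `-Inf`/`Inf`).
#' @param L,U limiting bounds; default to `l` and `u` (no relaxation room).
#' @param mode `"absolute"` (default) or `"relative"` (multiples of `d`).
#' @return An object of class `range_restrictions`.
#' @examples
#' range_restrictions(l = 0, u = 20)
#' range_restrictions(l = 0.5, u = 3.5, mode = "relative")
#' @export
range_restrictions <- function(l = 0, u = Inf, L = NULL, U = NULL,
                               mode = c("absolute", "relative")) {
  mode <- match.arg(mode)
  if (is.null(L)) L <- l
  if (is.null(U)) U <- u
  structure(list(l = as.numeric(l), u = as.numeric(u),
                 L = as.numeric(L), U = as.numeric(U), mode = mode),
            class = "range_restrictions")
}

## expand a bound (scalar or length-n) to a per-unit absolute vector
.expand_bound <- function(b, n, d, relative) {
  b <- rep_len(b, n)
  if (relative) {
    fin <- is.finite(b)
    b[fin] <- b[fin] * d[fin]
  }
  b
}

#' Build the benchmark (design) matrix
#'
#' Column `j` holds, for every sampled unit, its contribution to constraint
#' `j` of `spec`: a 0/1 cell-membership indicator for categorical
#' cross-classifications, the unit's value for a continuous constraint, and
#' 1 for the all-units constraint `"*"`. Columns follow the order of `spec`.
#'
#' @param sample a [sample_data()] object.
#' @param spec a [benchmark_spec()].
#' @return A sparse `n x p` matrix (`Matrix::dgCMatrix`) with constraint
#'   labels as column names.
#' @examples
#' s <- sample_data(data.frame(unit_id = 1:3, weight = 1,
#'                             gender = c("F", "F", "M")))
#' spec <- benchmark_spec(c("gender", "gender"), c("F", "M"), c(2, 1))
#' as.matrix(build_design_matrix(s, spec))
#' @export
build_design_matrix <- function(sample, spec) {
  stopifnot(inherits(sample, "sample_data"), inherits(spec, "benchmark_spec"))
  n <- sample$n
  p <- nrow(spec)
  cols <- vector("list", p)
  labs <- character(p)
  for (j in seq_len(p)) {
    vnames <- trimws(strsplit(spec$variables[j], ";", fixed = TRUE)[[1]])
    if (identical(vnames, "*")) {
      cols[[j]] <- rep(1, n)
      labs[j] <- "(all)"
      next
    }
    missing_v <- setdiff(vnames, names(sample$variables))
    if (length(missing_v)) {
      stop("constraint ", j, " ('", spec$variables[j],
           "'): unknown variable(s) ", paste(missing_v, collapse = ", "))
    }
    if (is.na(spec$categories[j])) {
      if (length(vnames) != 1L) {
        stop("constraint ", j, ": continuous constraints use one variable")
      }
      val <- sample$variables[[vnames]]
      if (!is.numeric(val)) {
        stop("constraint ", j, " ('", vnames,
             "'): no categories given but variable is not numeric")
      }
      cols[[j]] <- as.numeric(val)
      labs[j] <- vnames
      next
    }
    cats <- trimws(strsplit(spec$categories[j], ";", fixed = TRUE)[[1]])
    if (length(cats) != length(vnames)) {
      stop("constraint ", j, ": ", length(vnames), " variables but ",
           length(cats), " category labels")
    }
    memb <- rep(TRUE, n)
    for (k in seq_along(vnames)) {
      col <- sample$variables[[vnames[k]]]
      known <- if (is.factor(col)) levels(col) else unique(trimws(as.character(col)))
      if (!cats[k] %in% known) {
        stop("constraint ", j, " ('", spec$variables[j], "'): category '",
             cats[k], "' not a known label of variable '", vnames[k], "'")
      }
      memb <- memb & trimws(as.character(col)) == cats[k]
    }
    cols[[j]] <- as.numeric(memb)
    labs[j] <- paste0(spec$variables[j], "=", spec$categories[j])
  }
  X <- Matrix::Matrix(do.call(cbind, cols), sparse = TRUE)
  X <- methods::as(methods::as(X, "generalMatrix"), "CsparseMatrix")
  dimnames(X) <- list(NULL, make.unique(labs))
  X
}

#' Assemble a range-restricted calibration problem
#'
#' Builds the object consumed by every solver in the package: the benchmark
#' matrix `X`, the target totals `t_x`, the initial weights `d`, and the
#' range restrictions expanded to absolute per-unit bound vectors.
#'
#' @param sample a [sample_data()] object.
#' @param benchmarks a [benchmark_spec()].
#' @param rr a [range_restrictions()] object (default: positivity only).
#' @param norm `"l1"` (total absolute error, the default) or `"linf"`
#'   (largest single error, shared error variable across non-exact
#'   constraints). In `"linf"` mode the constraint weights `r` are ignored.
#' @param kappa_gb optional Gelman bound: a cap on the ratio of the largest
#'   to the smallest calibrated weight, added to all solves as linear
#'   constraints through two auxiliary scalars.
#' @return An object of class `calibration_problem`.
#' @examples
#' pr <- intro_example(u = 20)
#' pr
#' @export
calibration_problem <- function(sample, benchmarks,
                                rr = range_restrictions(),
                                norm = c("l1", "linf"), kappa_gb = NULL) {
  norm <- match.arg(norm)
  stopifnot(inherits(sample, "sample_data"),
            inherits(benchmarks, "benchmark_spec"),
            inherits(rr, "range_restrictions"))
  if (!is.null(kappa_gb)) {
    stopifnot(is.numeric(kappa_gb), length(kappa_gb) == 1L, kappa_gb > 0)
  }
  n <- sample$n
  X <- build_design_matrix(sample, benchmarks)
  rel <- rr$mode == "relative"
  l <- .expand_bound(rr$l, n, sample$d, rel)
  u <- .expand_bound(rr$u, n, sample$d, rel)
  L <- .expand_bound(rr$L, n, sample$d, rel)
  U <- .expand_bound(rr$U, n, sample$d, rel)
  structure(list(X = X, d = sample$d, t_x = benchmarks$total,
                 n = n, p = nrow(benchmarks),
                 exact = benchmarks$exact, r = benchmarks$r,
                 v = benchmarks$v, eps_cap = benchmarks$eps_cap,
                 l = l, u = u, L = L, U = U,
                 norm = norm, kappa_gb = kappa_gb,
                 spec = benchmarks, sample = sample,
                 normalised = FALSE),
            class = "calibration_problem")
}

#' @export
print.calibration_problem <- function(x, ...) {
  cat("<calibration_problem> n =", x$n, "units, p =", x$p, "constraints (",
      sum(x$exact), "exact );", "norm =", x$norm,
      if (!is.null(x$kappa_gb)) paste("; Gelman bound", x$kappa_gb), "\n")
  cat("  sum(d) =", format(sum(x$d)),
      " sum(t_x) =", format(sum(x$t_x)), "\n")
  invisible(x)
}

#' Normalise benchmark totals by table totals
#'
#' Divides `t_x[j]` and column `j` of `X` by the normalisation total `v[j]`
#' wherever `v` is given, so each constraint is expressed as a proportion of
#' its benchmark table and per-constraint errors become comparable across
#' tables. The feasible set of weight vectors is unchanged: `w` satisfies the
#' scaled constraint within scaled tolerance iff it satisfies the original.
#'
#' @param problem a [calibration_problem()].
#' @return An equivalent, rescaled `calibration_problem`.
#' @export
apply_normalisation <- function(problem) {
  stopifnot(inherits(problem, "calibration_problem"))
  v <- problem$v
  idx <- which(!is.na(v))
  if (!length(idx)) return(problem)
  if (any(v[idx] <= 0)) stop("apply_normalisation: v must be positive")
  out <- problem
  out$t_x[idx] <- problem$t_x[idx] / v[idx]
  scale <- rep(1, problem$p)
  scale[idx] <- 1 / v[idx]
  out$X <- problem$X %*% Matrix::Diagonal(x = scale)
  dimnames(out$X) <- dimnames(problem$X)
  out$normalised <- TRUE
  out
}

#' Validate a calibration problem
#'
#' Report-only diagnostic pass: flags dimension mismatches, non-positive
#' initial weights, bound-order violations, non-finite entries, and
#' structurally unreachable constraints (an all-zero benchmark column with a
#' positive target forces a minimum total absolute error of at least that
#' target). A valid problem yields a zero-row report.
#'
#' @param problem a [calibration_problem()].
#' @return data.frame with columns `issue` and `detail`; zero rows when the
#'   problem is valid.
#' @export
validate_problem <- function(problem) {
  stopifnot(inherits(problem, "calibration_problem"))
  iss <- list()
  add <- function(issue, detail) iss[[length(iss) + 1L]] <<- data.frame(
    issue = issue, detail = detail, stringsAsFactors = FALSE)
  with(problem, {
    if (nrow(X) != n || ncol(X) != p || length(t_x) != p) {
      add("dimension_mismatch",
          sprintf("X is %dx%d, n=%d, p=%d", nrow(X), ncol(X), n, length(t_x)))
    }
    if (any(d <= 0)) add("nonpositive_weights",
                         sprintf("%d units with d <= 0", sum(d <= 0)))
    if (any(l > u)) add("bound_order",
                        sprintf("l > u for %d unit(s)", sum(l > u)))
    if (any(L > l)) add("bound_order",
                        sprintf("L > l for %d unit(s)", sum(L > l)))
    if (any(u > U)) add("bound_order",
                        sprintf("u > U for %d unit(s)", sum(u > U)))
    if (any(!is.finite(t_x))) add("nonfinite_target", "t_x has NaN/Inf")
    if (any(!is.finite(X@x))) add("nonfinite_matrix", "X has NaN/Inf entries")
    dead <- which(Matrix::colSums(abs(X)) == 0 & t_x > 0)
    for (j in dead) {
      add("unreachable_constraint",
          sprintf("constraint %d has an all-zero sample column; %s %g",
                  j, "structurally unreachable, minimum error", t_x[j]))
    }
  })
  out <- if (length(iss)) do.call(rbind, iss) else
    data.frame(issue = character(0), detail = character(0))
  rownames(out) <- NULL
  out
}
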
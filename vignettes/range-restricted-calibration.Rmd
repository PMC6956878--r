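---
title: "Range-restricted survey calibration by global optimisation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Range-restricted survey calibration by global optimisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gocalib)
```

## The calibration problem

A sample of $n$ units comes with initial weights $\mathbf d > 0$ (typically
design weights) and an $n \times p$ benchmark matrix $\mathbf X$ whose
columns are 0/1 cell-membership indicators of categorical
cross-classifications, continuous variables, or the constant 1. Known
population totals $\mathbf t_x$ (e.g. census tabulations) define the
*benchmark constraints* (BC) $\mathbf X'\mathbf w = \mathbf t_x$, and
per-unit *range restrictions* (RR) $\mathbf l \le \mathbf w \le \mathbf u$
keep weights realistic. Calibration looks for

$$\arg\min_{\mathbf w}\; \mathscr G_{\mathbf d}(\mathbf w)
  \quad\text{s.t.}\quad \mathbf X'\mathbf w = \mathbf t_x,\;
  \mathbf l \le \mathbf w \le \mathbf u,$$

where the package minimises the modified chi-square (GREG) distance
$\mathscr G_{\mathbf d}(\mathbf w) = (\mathbf w-\mathbf d)'
\mathbf D^{-1}(\mathbf w-\mathbf d)$, $\mathbf D = \mathrm{diag}(\mathbf d)$.
Without RR the minimiser is the closed-form generalised-regression weight
vector (`greg_weights()`); the modified discrimination information distance
of raking is provided for evaluation (`mdi_distance()`) but not solved for.

With realistic benchmark tables this constraint system is frequently
*infeasible*: fine cross-tabulations contain cells with no sampled unit,
totals assembled from different sources (or disclosure-control noise) are
mutually inconsistent, and tight RR shrink the reachable set. Iterative
calibration software then simply fails to converge. The package's approach
is to *certify feasibility first* and repair the problem minimally and
transparently when it fails.

## The feasibility layer

Three linear programs, all built from the same auxiliary-variable encoding
of the $\ell_1$ error $\lVert\mathbf X'\mathbf w - \mathbf t_x\rVert_1 \le
\mathbf 1'\tilde\varepsilon$, $\tilde\varepsilon \ge 0$:

* `min_tae()` — the minimum total absolute error (TAE\*) in the non-exact
  BC compatible with the RR box: the problem is feasible iff TAE\* = 0.
  Per-constraint weights $r_j$ give a weighted $\ell_1$ objective
  $\sum_j r_j\tilde\varepsilon_j$.
* `min_tae_at_limits()` — the same minimum (TAE\*\*) over the outer
  *limiting* box $[\mathbf L, \mathbf U]$: the error that remains
  unavoidable no matter how far the bounds may legally move.
* `min_tac()` — the minimum total absolute change (TAC\*)
  $\sum\lambda_i + \sum\mu_i$ of lower/upper bounds (inside
  $[\mathbf L,\mathbf U]$) such that the BC error can be kept below a
  user tolerance $\varepsilon$.

Exact constraints are equality rows without error variables — exactness is
structural, not a large-penalty limit. The `"linf"` norm mode shares one
scalar error across non-exact constraints (minimax error); the constraint
weights `r` are ignored in that mode, since rescaling rows would change the
units of the reported error. A Gelman ratio bound
$\max_i w_i / \min_i w_i \le \kappa$ is available as linear constraints
through two auxiliary scalars $\alpha,\beta$.

Two details the formulation leaves open were resolved as follows. First,
per-constraint "precision levels" are implemented as *upper bounds*
$\tilde\varepsilon_j \le c_j$ (argument `eps_cap`), not as fixed values:
fixing an error from above *and* below would make well-posed problems
infeasible for no operational gain. A cap below what the box permits is a
structural infeasibility and is reported exactly like incompatible exact
constraints. Second, the one-parameter (`uniform`) bound-change mode
minimises the shared scalars with the per-unit expansion as its objective
weight, so the reported TAC\* is always $\sum\lambda_i + \sum\mu_i$
regardless of mode.

## The calibration layer

`solve_restricted()` minimises the chi-square distance subject to the RR
box, exact BC equalities, and the weighted $\ell_1$ ball
$\sum_j r_j|\mathbf x_j'\mathbf w - t_j| \le \text{budget}$, linearised
with the same auxiliary variables as the feasibility LPs — a convex
quadratic program solved to certified global optimality.

`go_calibrate()` is the two-step driver: compute TAE\*, then calibrate with
budget TAE\* (zero when feasible). Convergence is guaranteed by
construction for every problem whose exact constraints are compatible with
the RR — the only structural failure mode, reported as such before any
calibration is attempted.

`go_calibrate_relaxed(problem, eps)` adds the bound-repair branch: when
$\varepsilon \ge$ TAE\* it reduces exactly to `go_calibrate()`; when
TAE\*\* $\le \varepsilon <$ TAE\* it fixes the minimal bound change
$(\lambda^\ast,\mu^\ast)$ from `min_tac()` and calibrates inside the
relaxed box with budget $\varepsilon$; when $\varepsilon <$ TAE\*\* the
request is unattainable and $\varepsilon$ is replaced by TAE\*\*, recorded
in the result. The final solve deliberately *fixes* the bound modification
rather than re-optimising bounds and weights jointly: the two-step reading
keeps the distance objective's domain deterministic, and the
non-uniqueness of $(\lambda^\ast,\mu^\ast)$ is recorded in the result
object.

## One solver, and why it is in the package

Every optimisation above is a linear program or a convex quadratic program
whose Hessian is diagonal ($2\mathbf D^{-1}$ on the weights, zero on the
auxiliary variables). The package ships a single sparse primal-dual
interior-point method (Mehrotra predictor-corrector, infeasible start)
covering both, with the constraint matrices assembled sparse — each error
row touches one auxiliary variable plus one benchmark column.

Numerical choices:

* Feasibility decisions use the scale-free tolerance
  $\text{TAE}^\ast \le 10^{-8}\max(1, \lVert\mathbf t_x\rVert_1)$.
* Solver targets: relative primal/dual residuals and complementarity gap
  $\le 10^{-9}$ (gap relative to $1+|\text{objective}|$). Near degenerate
  optima (a budget row exactly tight) iterates can drift after
  complementarity is exhausted; the solver then returns the most accurate
  iterate seen and accepts it only within $10^3\times$ the residual target
  and $10^{-5}$ relative gap. The calibration drivers additionally verify
  the returned point against the budget and the exact constraints at
  domain tolerances.
* The error budget handed from the LP to the QP is inflated to
  $\text{TAE}^\ast(1+10^{-6}) + 10^{-9}$: the LP optimum is certified only
  to the solver's gap, and an exactly-tight ball can have an empty
  numerical interior.
* Linearly dependent equality rows (two exact partitions of the same
  population) are dropped by QR before factorisation; equality-row
  *consistency* is guaranteed by an always-feasible pre-check LP that
  minimises the exact-subset error alone.
* All solves the package issues are feasible by construction: min-TAE LPs
  are always feasible, `min_tac()` pre-compares $\varepsilon$ with
  TAE\*\*, and the calibration budget is certified first. The solver
  therefore never needs an infeasibility certificate.
* Infinite bounds are kept as infinities and never become large finite
  numbers; free linear variables are split internally into differences of
  nonnegative parts; variables with equal bounds are substituted out.

The closed-form GREG weights, `quadprog`'s dual active-set method (on
problems expressible without auxiliary variables), and exhaustive grid
search on tiny instances serve as independent cross-checks of this engine
in the test suite — never as the production path.

## Estimation

`estimate_totals()` computes $\mathbf Y'\mathbf w$ (Horvitz–Thompson with
$\mathbf w = \mathbf d$). `jackknife_sd()` implements the delete-a-group
jackknife over PSUs: groups from a seeded shuffle with systematic
assignment, per-replicate rescaling of the initial weights by $G/(G-1)$,
full recalibration per replicate, and
$\widehat{SD} = \sqrt{\tfrac{G-1}{G}\sum_g(\hat\theta_{(g)} -
\hat\theta)^2}$ centred at the full-sample estimate. Centring at the
replicate mean is a known variant; the full-sample centring is stated here
because the two differ on small $G$. Replicates that fail structurally are
excluded and counted in the output.

`error_metrics()` reports TAE, TAE as a percentage of the population size,
the total relative error TRE (%) over cells with positive reference value
— zero-reference cells are excluded and counted, avoiding division by
zero — and RMSE. `weight_diagnostics()` reports the chi-square distance
(raw, and per unit, since conventions differ on the scale), quartiles with
linear interpolation between order statistics (R's default type 7,
applied consistently), and the max/min ratio with $\infty$ when the
minimum is nonpositive.

## The synthetic scenario, and what it does not show

`generate_scenario()` emulates the structure of calibrating a national
health survey to census tables: a population cross-classified by region
$\times$ gender $\times$ fine age band, an activity class correlated with
age that is never benchmarked (the validation variable), a fine benchmark
table used as inexact constraints, and broad gender-by-age and region
tables imposed exactly. Defaults: population 100,000; sample 1,000 drawn
without replacement ($d = N/n$; a stratified-by-region option gives
inverse-inclusion weights); 3 regions $\times$ 2 genders $\times$ 12 fine
age bands (72 fine cells, 4 broad bands); fine-cell probabilities from a
symmetric Dirichlet with concentration 2, which typically leaves one or
two fine cells empty in the sample — the structural infeasibility the
method is designed for — while keeping most cells small-but-occupied;
multiplicative benchmark perturbation $\delta = 0.02$ (factors uniform in
$[1-\delta, 1+\delta]$, emulating disclosure-control noise and making the
fine system inconsistent); 20 PSUs per region. Everything is a pure
function of the seed.

`scenario_experiments()` runs the standard three-regime design — Ex1
positivity only, Ex2 bounds $0.5\,\mathbf d \le \mathbf w \le
3.5\,\mathbf d$, Ex3 minimal change of the Ex2 bounds inside
$[0, 10\,\mathbf d]$ with a 0.1% error tolerance — each against a
Horvitz–Thompson reference row.

What passing these studies shows is structural: orderings (tighter bounds
cannot decrease the minimum error; the bound ratio cap is enforced),
exact recovery when the benchmarks are consistent, and variance reduction
on benchmarked totals. What they cannot show: the generator draws
activity from a smooth age profile, has no nonresponse, no measurement
error, no informative sampling, and its benchmark tables are perturbed
independently per cell — real census-versus-survey discrepancies are
none of those things, so error *magnitudes* on real data will differ even
where the orderings persist.

The packaged studies use problem sizes chosen to make the full battery
(hundreds of calibrations, a 30-group jackknife with per-replicate
recalibration, 20-seed repetitions) run in about a minute of CPU; the
solver itself handles the default scenario (1,000 units, 83 constraints)
in well under a second per calibration, and scales as a sparse IPM in the
number of constraints rather than units.

## Known limitations

* Only the chi-square distance is solved for; raking under RR would need
  its own convex solve (the distance is evaluable for comparison).
* No penalised/ridge compromise between distance and BC error; the
  package's position is that the $\ell_1$ repair is more interpretable
  (its units are population counts) and certifies feasibility.
* No analytic (Taylor) variance estimators; the jackknife is the only
  variance path and costs one calibration per replicate group.
* Mixed continuous and categorical constraints are not co-scaled by
  default; constraints on very different scales should set the
  normalisation totals `v` (`apply_normalisation()`), otherwise the
  $\ell_1$ objective adds non-comparable units.
* PSU identifiers are the only design metadata; strata and
  finite-population corrections are out of scope.
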
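---
title: "Ignoring cross-loadings in confirmatory bifactor models: model, estimation and study design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ignoring cross-loadings in confirmatory bifactor models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bifactorsim)
```

## The model

`bifactorsim` studies a confirmatory bifactor measurement model for
p = 12 observed variables: one general factor on which every item loads,
and three orthogonal group factors with four primary indicators each.  The
population model additionally contains three *cross-loadings* — one item
per group factor loading on a neighbouring group factor.  In applied work
these are routinely fixed to zero "for simplicity"; the package quantifies
what that misspecification does to parameter estimates and to the popular
goodness-of-fit indices.

With loading matrix $\Lambda$ (columns: general, group 1..3), orthonormal
factors and diagonal unique variances $\Theta$, the implied covariance is

$$\Sigma(\theta) = \Lambda\Lambda^\top + \Theta .$$

Generating values: all general loadings are 0.60; the primary group
loadings share one value $\lambda \in \{0.15, 0.30, 0.50, 0.60\}$; the
cross-loadings share one value $c \in \{0.05, 0.10, 0.20, 0.30, 0.40\}$.
Cross-loading placement is a fixed cyclic convention (item 4 on group 2,
item 8 on group 3, item 12 on group 1); by the symmetry of the design any
fixed placement is exchangeable, so nothing downstream depends on it.

### Error-variance convention

A literal reading of "error variances set to $1 - \lambda^2$" is ambiguous
for items loading on two or three factors.  The package's default is the
**unit-variance convention**: $\theta_i = 1 - \sum_k \lambda_{ik}^2$, so
every item has total variance exactly 1 and communalities read directly
off the loadings.  The per-group literal reading
($\theta_i = 1 - \lambda_i^2$ with $\lambda_i$ the primary group loading)
is available via `variance_convention = "literal"`.  The unit convention is
the default because it reproduces the published population-level behaviour
of the misspecified model: at $c = 0.40$ the population CFI across the
$\lambda$ grid spans roughly 0.91–0.99 with its minimum just above 0.91,
whereas the literal convention never drops below 0.95.  Both conventions
keep every $\Sigma$ positive definite over the whole grid.

```{r conventions}
sapply(c(0.15, 0.30, 0.50, 0.60), function(l)
  population_indices(bifactor_pattern(l, 0.40))$cfi)
```

## Data generation

Samples are multivariate normal with mean zero (loadings and covariances
are location-invariant) via the Cholesky factor of $\Sigma$, and only the
sample covariance matrix $S$ (divisor $n-1$) is retained: all normal-theory
quantities depend on the data through $(S, n)$.  Seeding is counter-based —
`seed_for(condition, replication, attempt)` maps injectively into
$[0, 2^{31}-1)$ from one master seed — so studies are byte-reproducible and
order-independent under parallel execution.

## Estimation

Models are fitted by minimising the Wishart maximum-likelihood discrepancy

$$F(S, \Sigma) = \log|\Sigma| - \log|S| + \mathrm{tr}(S\Sigma^{-1}) - p,$$

with the chi-square statistic $T = (n-1)\hat F$, matching the $n-1$
divisor of $S$.  Unique variances are deliberately **unconstrained**:
improper ("Heywood") solutions with negative $\hat\theta_i$ must remain
observable because their incidence is itself a study outcome.  The search
runs BFGS (cap 150 iterations) from neutral starts — loadings at half the
item standard deviation, unique variances at half the item variance — and
then polishes with Fisher scoring (cap 50 steps, step-halving), for which
the compiled information-matrix kernel gives quadratic convergence where
the quasi-Newton curvature estimate stalls.  Convergence is declared when
the gradient max-norm is at most `1e-6`; a non-positive-definite
$\Sigma(\theta)$ during the search is handled by a finite penalty.

Two failure modes matter, and both are genuine features of unconstrained
ML on weakly identified bifactor structures rather than optimizer
artifacts (restarts from the generating values and from
small-group-loading starts reach the same solutions):

* **Heywood case** — a converged solution with some $\hat\theta_i < 0$,
  typically a group factor collapsing onto a single item;
* **nonconvergence** — the discrepancy decreases along an unbounded
  improper path, so no interior optimum exists and the gradient never
  vanishes within the iteration budget.

For the correctly specified model both concentrate sharply at
$\lambda = 0.15$ with small $N$ and are essentially absent for
$\lambda \ge 0.50, N \ge 500$.  Fitting the strongly misspecified variant
($c \ge 0.30$ with strong group loadings) adds an improper-solution mode
of its own at any sample size: the strain of absorbing the ignored
cross-loadings pushes a group factor toward collapse, and under the
unit-variance convention the sample discrepancy often keeps decreasing
along that improper path even though the population-level misspecified
optimum is proper.  Absolute rates are optimizer-dependent (tolerances,
stopping rules and start values move them), so the package's tests assert
only their ordering across conditions, never levels.

## Fit indices

For a fitted model the package reports $T$, RMSEA, CFI (independence
baseline), the ML GFI, the naive SRMR, the asymptotically unbiased SRMR,
the average communality $\bar R^2$, and the communality-corrected ratio
$\mathrm{SRMR}_u/\bar R^2$ with cutoffs 0.05 (close fit) and 0.10
(adequate fit).  SRMR residuals use the correlation metric over all
$p(p+1)/2$ non-duplicated elements, diagonal included (the dominant
software definition; `include_diagonal = FALSE` gives the off-diagonal
variant for sensitivity checks).

The unbiased SRMR subtracts from each squared standardized residual an
estimate of its sampling variance before averaging, truncating the
aggregate at zero:
$\mathrm{SRMR}_u = \sqrt{\max(0, \overline{r^2_{ij} - v_{ij}})}$.
The $v_{ij}$ come from the normal-theory asymptotic covariance of the
sample moments projected through the model,
$\Omega = \Gamma - \Delta(\Delta^\top\Gamma^{-1}\Delta)^{-1}\Delta^\top$,
rescaled to the correlation metric and divided by $n-1$.  Aggregate (not
per-element) truncation is used: it keeps the estimator mean-unbiased for
well-fitting models — the package verifies by simulation that its mean at
$N = 100$ sits near the population SRMR while the naive SRMR is strongly
biased upward — whereas per-element truncation inflates the mean and makes
the index strongly sample-size dependent, contradicting its purpose.

Population-level indices are obtained by fitting a structure to a
population $\Sigma$ directly: $\mathrm{RMSEA} = \sqrt{F_0/\mathrm{df}}$,
$\mathrm{CFI} = 1 - F_0/F_{0B}$, GFI/SRMR from $(\Sigma, \hat\Sigma)$, and
$\mathrm{SRMR}_u = \mathrm{SRMR}$ (no sampling error).  They are
deterministic and reproduce the reliability paradox: at fixed
misspecification, RMSEA and SRMR worsen while CFI and GFI *improve* as
loadings shrink.

RMSEA confidence intervals and the test of close fit are declared but not
implemented; no result here depends on them.

## Recovery metrics

Recovery is the RMSD between generating and estimated loadings,
$\sqrt{\sum_i (\lambda_{i}^{(t)} - \lambda_{i}^{(e)})^2 / p}$, computed
separately for the 12 general loadings, the 12 primary group loadings and
(correct-model fits only) the 3 cross-loadings, after per-column sign
alignment — ML factor solutions are sign-indeterminate, and an unaligned
flip would spuriously inflate an RMSD to about $2\lambda$.  Signed mean
biases (estimated minus theoretical) accompany each subset; values at or
below 0.20 are conventionally deemed satisfactory.

## The study engine

The full design crosses model specification (correct vs. cross-loadings
omitted), $N \in \{100, 200, 500, 1000\}$, $\lambda$ and $c$: 160 cells.
Each cell draws fresh samples until the requested number of converged,
non-Heywood solutions exists (attempt cap: 10 times the target), logging
every attempt for the nonconvergence/Heywood analyses.  Replacement —
rather than post-hoc deletion — keeps the design balanced, so the
factorial ANOVA's sequential and partial sums of squares coincide; balance
is asserted before fitting and the $\lambda = 0.15, N = 100$ cells are the
only ones that can run short at the attempt cap.

The meta-model fits all main effects and interactions of the four design
factors to each dependent variable and reports partial
$\eta^2 = SS_{\mathrm{effect}}/(SS_{\mathrm{effect}} + SS_{\mathrm{error}})$,
tagged by the conventional bands (below 0.05 negligible, 0.05–0.10 small,
0.10–0.20 medium, above 0.20 large).  p-values are reported but never used
as a decision surface: with tens of thousands of records everything is
"significant".  For cross-loading recovery the specification factor is
dropped (cross-loadings exist only in correct-model fits).  Incidence of
nonconvergence and Heywood cases is analysed with a binomial logit on main
effects plus two-way interactions, ranked by sequential deviance; under
quasi-separation each design cell receives two half-weight
pseudo-attempts, one per outcome, and a warning.

### Problem sizes

The package's scaled default is 100 good replications per cell; the
published full scale (1000) is one argument away
(`run_study(reps = 1000)`).  The acceptance script and the test suite use
50 replications per cell — about 9,000 ML fits including replacements —
which stabilises the large effect sizes while keeping a full study run in
the minutes range on one core; the two cells behind the large-N RMSEA
check use 100 replications each.  Cell-level parallelism is available via
`workers` and cannot change results (the seed stream is per-attempt).

## What the generator does and does not emulate

The synthetic data are exactly multivariate normal with the stated
population structure: no excess kurtosis, no missing data, no categorical
items, no model error beyond the manipulated cross-loadings.  Passing
tests therefore validate the estimator, the indices and the study logic
under the normal-theory assumptions these statistics were derived for;
they say nothing about robustness to non-normality or coarse measurement.

Two further caveats on comparability with published full-scale results.
First, absolute nonconvergence/Heywood rates depend on optimizer policy;
this package's strict gradient criterion flags more weak-loading,
small-sample solutions than SEM software defaults do, so replacement
censors those cells more heavily.  Second, the exact small-sample
distribution of the chi-square-based indices is sensitive to the software
pipeline; the package's values are internally consistent with
normal-theory expectations (its residual-variance projection matches the
observed residual dispersion, and GFI obeys the small-sample arithmetic
$\mathrm{GFI} \approx 1 - 2\hat F/p$), which is the defensible reference
point for a reimplementation.

## Numerical choices

* Penalty, not projection, for non-positive-definite $\Sigma(\theta)$
  during the search; tie-breaks never arise because the discrepancy is
  smooth in the free parameters.
* Degenerate inputs error early and loudly: non-PD population $\Sigma$
  names the offending condition; singular sample covariances are flagged
  and replaced by the study engine.
* The information matrix in the scoring step carries a `1e-8` ridge; the
  residual-variance projection falls back to a pseudo-inverse with a
  warning if the Jacobian cross-product is singular.
* CFI is clamped to $[0, 1]$ and defined as 1 when both noncentrality
  estimates vanish; per-item communalities are clamped to $[0, 1]$ (with a
  warning for Heywood solutions) before averaging.
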
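---
title: "Structured antedependence models for longitudinal residual feed intake"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structured antedependence models for longitudinal residual feed intake}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Residual feed intake (RFI) measures feed efficiency as the difference between
an animal's actual feed intake (FI) and the intake predicted from its
production and maintenance requirements — in growing pigs, typically average
daily gain (ADG), metabolic body weight (MBW = BW^0.6) and backfat thickness
(BF). When FI and the production traits are recorded weekly, RFI becomes a
*trajectory*, and the genetic analysis must model covariances both between
time points and between traits. `longsad` implements two longitudinal RFI
criteria in a pedigreed animal model:

* the **phenotypic regression model**: a single-response model for FI with
  week-specific fixed regressions on the production phenotypes; the residual
  decomposition of the adjusted intake defines RFI. Its known weakness is
  that the resulting RFI is generally *not* genetically independent of the
  production traits.
* the **multi-SAD regression model**: a joint model for all four traits in
  which the genetic and environmental effects of FI regress on the
  contemporaneous effects of the production traits with separate
  coefficients per component. Adjusting the FI effects with the *genetic*
  coefficients yields RFI\*, which is genetically independent of the
  production traits at every time point by construction.

## The structured antedependence (SAD) model

A first-order SAD process for a random effect over weeks $t_1 < \dots < t_n$
is

$$u_j = \theta_j\, u_{j-1} + \varepsilon_j, \qquad
  \varepsilon_j \sim N(0, \sigma^2_j),$$

with no lag term at the first week. The antedependence parameter is a
polynomial of time, $\theta_j = \sum_q a_q t_j^q$, and the innovation
variance is log-polynomial, $\sigma^2_j = \exp(\sum_q d_q t_j^q)$, which
keeps it positive without constraints on the coefficients. Writing $L$ for
the unit-lower-triangular matrix carrying $-\theta_j$ on its first
subdiagonal and $D$ for the diagonal of innovation variances, the implied
covariance satisfies $\Sigma^{-1} = L' D^{-1} L$; `covariance_from_factors()`
builds $\Sigma$ by triangular solves. The shorthand SAD$\beta\gamma$ names
the degrees of the $\theta$ and $\log\sigma^2$ polynomials.

The multi-trait extension stacks the four traits (order ADG, MBW, BF, FI;
the regressed trait last) and adds *cross-antedependence* rows for FI:

$$u_{FI,j} = \theta_{uFI,j} u_{FI,j-1}
  + b_{u,ADG,j} u_{ADG,j} + b_{u,MBW,j} u_{MBW,j} + b_{u,BF,j} u_{BF,j}
  + \varepsilon_{uFI,j},$$

and identically for the environmental component with coefficients $b_e$.
The cross coefficients are themselves polynomials of time (degree 1 in the
retained model). Production traits are mutually independent — their
covariances with FI arise only through the FI rows. The joint covariance is
again $L^{-1} D L^{-T}$ for the joint regression operator, so every
covariance matrix in the package is assembled by one code path
(`multi_trait_covariance()`), validated against direct Monte-Carlo
simulation of the defining recursions (the universal oracle of the test
suite).

### RFI\* and its covariances

Substituting the FI recursion into the adjustment recursion

$$u^*_{RFI,j} = u_{FI,j} + \theta_{uFI,j}(u^*_{RFI,j-1} - u_{FI,j-1})
  - \textstyle\sum_s b_{u,s,j}\, u_{s,j}$$

collapses RFI\* to a pure antedependence process driven by the FI genetic
innovations: $u^*_j = \theta_{uFI,j} u^*_{j-1} + \varepsilon_{uFI,j}$. Hence
$G^*$ is built from FI's genetic $\theta$ and innovation variances alone
(cross terms excluded), and $u^*$ is uncorrelated with every production
effect at every week pair — the model's headline property, verified both by
simulation and exactly through the implied linear operator in the tests.

The environmental covariance of RFI\* and the production traits is
$P^* = B P_T B'$, where $P_T$ is the joint environmental covariance and $B$
is block lower triangular with identity diagonal blocks and FI-row blocks
$b_{s/FI}$ whose entry $(j, m)$, $m \le j$, is
$-(\prod_{k=m+1}^{j} \theta_{eFI,k})\, b_{u,s,m}$ (empty product = 1). This
is the unrolled form of the $e^*$ recursion; the test suite checks that
applying $B$ to simulated environmental vectors reproduces the recursion to
machine precision. As printed, the $e^*$ adjustment uses the *genetic*
coefficients $b_u$; `use_be = TRUE` substitutes the environmental
coefficients, which produces an RFI independent of production traits at both
the genetic and phenotypic levels. The default follows the defining
equations; the variant is surfaced, never silently chosen.

A note on interpretation: the genetic regression coefficients reported by
`regression_trajectories()` are the cross-antedependence polynomials
evaluated per week. The contemporaneous ratio
$\mathrm{cov}_u(s_j, FI_j)/\sigma^2_{u,s_j}$ coincides with that polynomial
only when FI carries no antedependence on its own past (the lag term
otherwise feeds week-$(j-1)$ production effects into $u_{FI,j}$); the two
agree at the first week always.

## REML estimation

The observation model is $y = X\beta + Zu + e$ with
$u \sim N(0, A \otimes \Sigma_g)$ over pedigree animals ($A$ the numerator
relationship matrix with exact inbreeding, tabular method) and
$e \sim N(0, I \otimes \Sigma_e)$ over phenotyped animals. Fixed effects are
week-specific intercepts per trait by default; arbitrary per-trait formulas
are supported, and the phenotypic regression model places the week-nested
production covariates here. Missing cells are dropped from the likelihood,
never imputed; linear interpolation is an explicit preprocessing step
(`interpolate_missing()`), mirroring the two analyses (with and without
completion) such designs require.

Two numerically identical evaluation paths are implemented:

* **eigendecomposition path** (complete records): rotate animals by the
  eigenvectors of the phenotyped block of $A$, then simultaneously
  diagonalise $\Sigma_g$ against $\Sigma_e$; each likelihood evaluation then
  costs one $q \times q$ eigendecomposition plus vectorised scalar work
  ($q$ = traits × weeks). With cell-mean designs an additional closed form
  reduces the fixed-effect projection to $O(Nq)$. This is what makes joint
  4-trait, 10-week fits on ~600–1000 animals run in seconds to tens of
  seconds on one CPU.
* **sparse mixed-model-equations path** (any missingness): Henderson's
  equations with the sparse $A^{-1}$ (Henderson's rules with exact
  inbreeding) and a sparse Cholesky of the coefficient matrix, using the
  standard determinant identity
  $\log|V| + \log|X'V^{-1}X| = \log|R| + \log|G| + \log|C|$.

Both paths are tested to $10^{-8}$ against an independently coded dense
projection-form REML criterion. Maximisation is quasi-Newton (BFGS) with
numerical gradients on the unconstrained coefficient vector; the
finite-difference Hessian at the optimum provides the information matrix
$I(\hat\omega)$, whose condition number $\sqrt{\lambda_{max}/\lambda_{min}}$
is the practical identifiability diagnostic (flag threshold 1000 by
default, configurable). Convergence uses a relative log-likelihood change
below $10^{-10}$ within `optim`'s BFGS, with jittered restarts on failure;
these tolerances are this package's choice.

The **two-stage scheme** (`two_stage = TRUE`, the default for the joint
model) first fits each production trait alone and freezes its
antedependence and innovation parameters at those estimates in the joint
fit, cutting the joint search to FI and cross parameters (21 free
parameters in the retained model). The two-stage constraint is exact in the
model: production traits carry no cross terms, so their marginal processes
are their single-trait SAD processes.

**Degree selection** (`select_degrees()`) is forward stepwise: per trait,
all admissible single-degree increments (genetic/environmental ×
antedependence/innovation) are scored by likelihood-ratio test each cycle
and the most significant one below `alpha` (default 0.05, configurable) is
accepted, until none improves; then all cross-antedependence degrees are
increased together (joint LRT) while significant. Accepting the *best*
rather than the first significant move per cycle matters: testing moves in
a fixed order lets genuine environmental-variance misfit be absorbed by
genetic terms that happen to be tested earlier. Boundary cases (a variance
parameter under the null) can use a 50:50 chi-square mixture p-value; the
naive chi-square is the default.

BLUP of the time-specific breeding values (TEBV) for *all* pedigree animals
(including unphenotyped ones) uses the mixed-model equations, or the
equivalent closed form in the eigen path; residual effects at unobserved
cells are set to their conditional expectations given the observed
residuals and flagged as such by construction of the output.

## Selection outputs

Eigendecomposition of the RFI genetic covariance summarises each animal's
TEBV trajectory: SBV1 (first eigenvector; all entries positive in
practice) tracks average efficiency over the test period, SBV2 the main
slope of the trajectory. Because SBV2's sign convention changes its
interpretation, eigenvector signs are fixed deterministically by making
each eigenvector's entry sum non-negative. Trajectories are clustered by
k-means (k = 3 by default, 25 restarts, fixed seed 20210625) with clusters
relabelled by ascending mean level; agreement between models is Cohen's
kappa after optimal label matching (labels from independent k-means runs
are arbitrary), and weekly EBV agreement uses Spearman correlations with
Fisher-z intervals.

## The synthetic-data generator

No real dataset ships with the package, so `sim_config()` /
`simulate_dataset()` emulate the motivating design: a multi-generation
pedigree (default 80 founders + 3 generations of 320, the last two
generations phenotyped, ~640 animals with records at default size — about
one quarter of the motivating population, chosen so a full analysis runs in
minutes on one CPU), 10 weekly time points, and the four traits in the
units that equalise their variances (ADG and FI in 10× g/d, MBW in 10×
kg^0.6, BF in 0.1× mm). Week means and trait-by-week missingness rates
default to the descriptive statistics of the emulated population
(`default_trait_tables()`); FI is essentially complete, BF is missing for
most animals in many weeks.

The generating SAD structures are the retained model forms
(`default_sad_spec()`): ADG SAD00/SAD00, MBW and BF SAD00/SAD01, FI
SAD11/SAD12, all cross-coefficient functions of degree 1. Cross-coefficient
trajectories use the reported week-1 values and slopes (genetic ADG
coefficient 1.13 at week 1 with slope −0.06, MBW 1.48 with slope −0.17, BF
constant 0.18; environmental analogues 0.92, 0.48 with slope −0.04, and
0.22 with slope 0.006). The antedependence and innovation coefficients are
not published; they were calibrated once, by minimising the mismatch
between the implied model quantities and the published summaries — weekly
phenotypic SDs, trait heritability trajectories (FI 0.20→0.39, ADG
0.32→0.39, MBW 0.21→0.60, BF 0.27→0.48), a stable moderate RFI\*
heritability (~0.14–0.16) and rising adjacent-week RFI genetic
correlations (~0.32→0.77) — and then frozen as `default_sad_params()`.

Genetic effects are drawn with covariance $A \otimes \Sigma_g$ (Cholesky of
$A$ mixed across animals), or equivalently by running the defining
recursions on innovations; both generators are exposed and tested to agree
distributionally. What the generator does **not** emulate: feeder-visit
behaviour, design-driven (non-random) missingness beyond per-cell rates,
selection within the generator, batch/sex structure unless explicitly
switched on, or any body-weight growth model — the optional latent BW track
is a package invention (back-transformed from simulated MBW) provided only
so the trait-derivation and interpolation operators can be exercised
end-to-end. Passing tests therefore demonstrate correctness of the
estimation machinery under the stated generative model, not robustness to
every feature of real feeding data.

## Validation design and problem sizes

The test suite's statistical checks run at sizes chosen for a single CPU;
every band scales with the simulation size, so smaller runs are not weaker
claims, only wider bands:

* covariance constructions vs recursion Monte-Carlo: 20 random parameter
  sets, 30,000 draws each, grids up to 5 weeks. Entry-wise 3-SE bands are
  applied with their expected chance exceedances: of a matrix's unique
  (upper-triangle) entries, at most max(2, 1%) may fall between 3 and 5
  SEs, none beyond 5.
* dense-REML agreement: a 5-animal, 2-week, 2-trait toy at 50 random
  parameter points, tolerance $10^{-8}$.
* coefficient-trajectory recovery: 5 replicates of the full default design
  (~640 phenotyped animals); every free coefficient must lie within 3
  information-based SEs of truth in at least 4 of 5 replicates.
* genetic independence of RFI\*: 200,000 Monte-Carlo draws at the default
  truth.
* likelihood-ratio calibration: 200 null replicates at ~200 animals;
  rejections must fall in the exact central 95% binomial region. A power
  companion checks a genuine antedependence slope is detected.
* model agreement under the independence condition: proportional
  genetic/environmental structures ($\Sigma_g = \lambda \Sigma_e$, under
  which $(1-h^2_P)\,\mathrm{cov}(u_{FI},u_P) = h^2_P\,\mathrm{cov}(e_{FI},e_P)$
  holds identically) with serially uncorrelated production effects, so the
  week-specific phenotypic regression is correctly specified; the two
  criteria's weekly EBVs must then agree (Spearman > 0.95).
* degree re-selection: 5 replicates at ~500 animals; the full generating
  specification must be re-found in a majority. This is the most fragile
  check by design: the single-trait step screens FI's *marginal* process,
  which under the joint truth is not exactly a SAD process, and the small
  quadratic innovation term of FI's environmental variance has limited
  power at this size.

## Known limitations

* Antedependence order is fixed at 1; higher-order lags are out of scope.
* Covariances among production traits are structurally zero, as in the
  model the package implements; if they matter for a dataset, the RFI\*
  independence argument no longer carries over unchanged.
* Dense per-animal algebra targets desk scale (roughly ≤ 3000 animals × 10
  weeks × 4 traits); national-evaluation scale would need sparse supernodal
  refactoring that deliberately is not attempted.
* Polynomials are evaluated at raw week indices 1..n by default (matching
  the field's usage); `scale_time = TRUE` maps the grid to [−1, 1] for
  conditioning with higher degrees, with coefficients then on that scale.
* The stepwise search is greedy; it returns a defensible model and its full
  decision trail, not a global optimum over specifications.
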
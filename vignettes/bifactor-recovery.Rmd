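---
title: "Regularized exploratory bifactor analysis: methods and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regularized exploratory bifactor analysis: methods and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rebifactor)
```

## The model

A bifactor structure assigns every item a loading on one general factor and
on exactly one of `f` group factors, all factors mutually orthogonal. The
exploratory route implemented here reaches that structure through a
second-order model: `f` correlated primary factors with independent-clusters
pattern `Λ` and correlation matrix `Φ`, a single second-order factor with
loadings `γ`, and disturbances `u² = 1 − γ²`. The Schmid-Leiman
orthogonalization converts the pair (first-order solution, second-order
solution) into the bifactor loading matrix

```
B = [ A γ | A diag(√u²) ],
```

with the algebraic identity `B B′ = A (γ γ′ + diag(u²)) A′`, so the
orthogonalized solution reproduces the oblique common part exactly. When
`Φ` is equicorrelated with common correlation `r ≥ 0` — as in every
population used here — the second-order solution is available analytically
(`γ_k = √r` for all `k`), which gives the closed-form population target
`population_bifactor_solution()`: general loadings `l√r`, group loadings
`l√(1−r)`. This analytic target is what sample solutions are scored
against; it coincides with what the sample pipeline produces on the
population matrix itself, a property the test suite checks for all 36
distinct populations.

## The two extraction engines

**ULS principal factoring** (`uls_extract()`) alternates the rank-`m`
eigen-approximation of the reduced matrix `R − diag(ψ)` with the
communality update `ψ ← 1 − rowSums(Λ²)`, starting from SMC-based
communalities, and stops when the least-squares criterion
`½‖R − ΛΛ′ − diag(ψ)‖²_F` decreases by less than `tol` (default `1e-3`,
cap 200 iterations). Negative `ψ` entries are allowed to develop during
iteration; propriety is judged at exit. This update is monotone: the
eigen step is the best positive-semidefinite rank-`m` approximation given
`ψ`, and the `ψ` update zeroes the diagonal residual, so the criterion
never increases (a property test asserts this).

**REFA** (`refa_extract()`) replaces the `p` free unique variances with one
shrinkage parameter: `Ψ = λ L̂`, where `L̂` is a non-iterative tentative
estimate. The default is `1 − SMC`, with SMC read off the inverse of `R`;
when `R` is singular — unavoidable in every cell with `N ≤ p` — a ridge of
`1e-3` is added before inversion, and the result is clipped to
`(1e-6, 1]`. A highest-correlation alternative (`1 − max_j |r_ij|`) is
available as `unique_method = "maxcor"`; in our experiments it changes
recovery very little, so SMC stays the default. For each `λ` the loadings
are the closed-form top-`m` eigen-solution of `R − λ diag(L̂)` (eigenvalues
floored at zero so loadings stay real on indefinite inputs), and `λ` is
chosen to minimize `ln det Σ + tr(R Σ⁻¹)` with `Σ = ΛΛ′ + λ diag(L̂)`. The
two constant terms of the classical ML fit function (`−ln det R − p`) are
dropped: they do not depend on `λ`, and `ln det R` does not exist for the
singular cells. The search uses 60 log-spaced values on
`(0.01, 0.999/max(L̂)]` followed by golden-section refinement of the
bracketing interval; the selected `λ*` is stable under grid doubling
(tested). Because `λ L̂ > 0`, REFA cannot produce a Heywood case — the
acceptance suite fuzzes 10,000 small-sample matrices without a single
improper extraction.

On population matrices with equal loadings the true model lies exactly on
the shrinkage path, so `λ* L̂` recovers the population unique variances to
the precision of the line search; this is one of the frozen oracle tests.

## Rotation

Direct quartimin (oblimin with γ = 0) is minimized by gradient projection
over oblique transforms with unit-length columns, starting from the
identity, tolerance `1e-6` on the projected-gradient norm, cap 1000
iterations, no Kaiser row normalization (switchable, default off, since
the procedure being emulated does not mention it). Two numerical details
matter:

- *Symmetric saddle.* For exactly symmetric inputs — population
  independent-clusters patterns — the identity transform is a stationary
  saddle of the criterion and the descent cannot leave it. When the first
  pass stalls on its very first step with a positive criterion, the
  algorithm restarts once from a fixed, deterministic slightly-oblique
  transform and keeps the better solution. Sample matrices essentially
  never trigger the restart, so the single-start replication economy is
  preserved; without it, population self-recovery is impossible.
- *Quartic flats.* When the global minimum is exactly zero (perfect simple
  structure is attainable) the projected gradient decays too slowly to
  meet the tolerance; iteration stops once the criterion is below `1e-11`
  and stagnant. The criterion sequence is non-increasing by construction
  (Armijo backtracking line search), which a property test asserts.

After rotation, every factor column is reflected so its loading sum is
positive, fixing the sign indeterminacy before the second-order stage.

## Second-order stage and propriety

With `f = 2` a one-factor model on a 2×2 correlation matrix is
under-identified; the conventional equal-loading solution `γ = √φ₁₂`,
`u² = 1 − φ₁₂` is used for both engines, and `φ₁₂ ≤ 0` marks the
replication improper — the factors simply do not share positive variance,
and the study design discards improper solutions rather than repairing
them. With `f ≥ 3` a single factor is extracted from `Φ̂` with the same
engine as the first stage; ULS disturbances are the fit's own
uniquenesses, REFA disturbances are `λ* L̂` of the second-order fit,
mirroring the first-order estimation. Disturbances are clipped to
`[0, 1]`; a clip exceeding 0.05 marks the stage improper.

A consequence worth stating plainly: although the REFA *extractor* can
never fail, the REFA *pipeline* can still be flagged improper when its own
quartimin solution orients the two primary factors with non-positive
correlation. On retained (ULS-proper) samples this affects roughly 2% of
records, concentrated in the `f = 2`, low-correlation, low-loading cells;
such records carry NA metrics and drop out of paired summaries.

## Recovery metrics

`align_solution()` resolves the permutation/reflection indeterminacy by
exhaustive search over the `f!` group-column orders (general column fixed)
with per-column optimal reflections, maximizing overall congruence; ties go
to the lexicographically smallest permutation, and the search refuses
`f > 6`. Congruence is the matrix-level Tucker coefficient computed after
an additional orthogonal Procrustes rotation toward the target. The two
RMSEs are computed on the permutation/reflection-aligned matrix *without*
Procrustes: a free orthogonal rotation would mix the general column into
the group block and make the separate general/group error report
meaningless. (A `procrustes_rmse` switch exposes the other reading; both
paths are tested.)

## The simulation design

`simulation_config()` defaults encode the study conditions: the full
factorial of N ∈ {10, 20, 30, 50}, p/f ∈ {4, 8}, f ∈ {2, 4},
l ∈ {0.40, 0.55, 0.70}, r ∈ {0.30, 0.50, 0.70} — 144 cells — with 100
retained replications per cell for the main study and 100 unscreened
replications for the improper-rate study. Samples are multivariate normal
via the Cholesky factor of the implied population correlation matrix, and
sample *correlation* (not covariance) matrices are analyzed, since the
populations are in correlation metric.

Screening is driven by the ULS pipeline: a sample is retained if and only
if ULS is proper on it, and then *both* engines are evaluated on the same
retained sample. This pairing is what makes the within-subject method
comparison (and its partial eta-squared,
`SS_M = (Σd)²/(2n)` against half the pooled within-cell sum of squares of
the paired differences) well defined. Fresh samples are drawn for the
screened study rather than reusing the unscreened ones; the seed scheme
`(master·7919 + cell·10⁵ + 2·replication + stream) mod (2³¹−1)` keeps
every (cell, replication, stream) triple on its own reproducible stream,
so runs replay bit-exactly and cells are schedule-independent work units.
A hard cap of 100 × `n_keep` attempts per cell prevents pathological
configurations from looping forever.

## Problem sizes used by the shipped checks

The acceptance script and the study-scale tests run the improper-rate
study at its full 100 replications per cell and the main study at 30
retained replications per cell (4,320 retained samples per method, about
13,000 pipeline fits in total). Grand means at this scale carry Monte
Carlo standard errors of about 0.001 on RMSE and 0.002–0.004 on
congruence, small enough for the comparisons the package reports.

## What the generator does and does not emulate

The populations are exact independent-clusters models: equal loadings
within a study cell, equicorrelated factors, no cross-loadings, no minor
factors, continuous multivariate-normal data. Passing recovery tests
therefore speak to estimator behavior under a *correctly specified* model
at small N. They say nothing about ordinal data, population model misfit,
unequal loadings, or non-normality — all realities of empirical data that
this design deliberately excludes. Results on real datasets should be
expected to be worse than the simulation suggests.

## Known limitations

- The improper-solution frequency of ULS at the smallest sample sizes
  depends strongly on the stopping rule of the principal-factoring
  iteration; with the loose `1e-3` criterion-decrease rule used here,
  non-convergence within 200 iterations essentially never occurs and
  impropriety is driven by Heywood cases and second-order failures.
- REFA's tentative uniquenesses lose almost all information when `R` is
  singular (`N ≤ p`): the ridge-regularized SMC collapses toward zero and
  `λ*` must compensate by orders of magnitude. The shrinkage path then
  still yields proper, usable solutions, but its advantage over ULS in
  those cells is modest.
- The exhaustive alignment cost grows factorially; it is capped at six
  group factors, far above the study's maximum of four.
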